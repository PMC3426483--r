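# Genome-scan outputs: the minor-allele-count threshold sweep, LOESS
# sliding-window differentiation profiles, and the sister-RAD-site
# correlation diagnostic.

# Per-site aggregation of a per-SNP table: for each RAD site keep the
# highest clipped FST among its passing positions (ties -> leftmost SNP).
aggregate_per_site <- function(tab, aggregation = c("max", "mean")) {
  aggregation <- match.arg(aggregation)
  if (nrow(tab) == 0L) return(tab[0, , drop = FALSE])
  o <- order(tab$site_id, -tab$fst, tab$position)
  t2 <- tab[o, , drop = FALSE]
  if (aggregation == "max") {
    out <- t2[!duplicated(t2$site_id), , drop = FALSE]
  } else {
    fst_mean <- tapply(t2$fst, t2$site_id, mean)
    out <- t2[!duplicated(t2$site_id), , drop = FALSE]
    out$fst <- as.numeric(fst_mean[out$site_id])
  }
  rownames(out) <- NULL
  out
}

#' Minor-allele-count threshold sweep
#'
#' For each threshold n, restricts the per-SNP table to SNPs whose pooled
#' minor allele count is at least n, and reports the number of surviving
#' SNPs and the mean clipped FST.  The mean is taken over per-RAD-site
#' values after max-aggregation by default (`per = "site"`); `per = "snp"`
#' averages over the SNPs themselves.
#'
#' @param tab a per-SNP table with columns site_id, position,
#'   minor_allele_count and clipped `fst` (see [add_fst()]).
#' @param n_range integer vector of thresholds (default 1:10).
#' @param per `"site"` or `"snp"`.
#' @return a data frame of class `sweep_summary` with columns n, snp_count
#'   and mean_fst (NA when no SNP survives).
#' @export
threshold_sweep <- function(tab, n_range = 1:10, per = c("site", "snp")) {
  per <- match.arg(per)
  rows <- lapply(n_range, function(n) {
    sub <- tab[tab$minor_allele_count >= n, , drop = FALSE]
    mean_fst <- if (nrow(sub) == 0L) NA_real_ else if (per == "site") {
      mean(aggregate_per_site(sub)$fst)
    } else mean(sub$fst)
    data.frame(n = n, snp_count = nrow(sub), mean_fst = mean_fst)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("sweep_summary", "data.frame")
  out
}

#' LOESS sliding-window differentiation profile
#'
#' Smooths per-site clipped FST along one chromosome by local polynomial
#' regression (2nd-order polynomial, tricube weights, span 0.4 of the
#' records, no robustness iterations), evaluated at every record position
#' and on a uniform grid for plotting.  Profiles are per chromosome and
#' never smoothed across chromosome boundaries.
#'
#' @param positions record positions (bp) on one chromosome.
#' @param fst clipped per-site FST values, same length.
#' @param span fraction of records in each local neighborhood.
#' @param degree local polynomial degree (falls back with a warning when
#'   there are fewer than degree + 2 records).
#' @param grid_step spacing of the uniform evaluation grid in bp (default
#'   1000; NULL for no grid).
#' @param chromosome chromosome name carried into the output.
#' @return an object of class `scan_profile`: a list with `profile` (data
#'   frame: position, smoothed, at_record), `span`, `degree`, `chromosome`.
#' @export
loess_profile <- function(positions, fst, span = 0.4, degree = 2L,
                          grid_step = 1000, chromosome = "chr1") {
  stopifnot(length(positions) == length(fst), span > 0)
  o <- order(positions)
  positions <- positions[o]; fst <- fst[o]
  n <- length(positions)
  while (degree > 0L && n < degree + 2L) {
    warning("only ", n, " records: falling back to degree ", degree - 1L)
    degree <- degree - 1L
  }
  if (n < 2L) stop("need at least two records for a profile")
  # guarantee each local neighborhood holds enough points for the fit
  span <- max(span, min(1, (degree + 2) / n))
  fit <- stats::loess(fst ~ positions, span = span, degree = degree,
                      family = "gaussian",
                      control = stats::loess.control(surface = "direct",
                                                     iterations = 1L))
  eval_pos <- positions
  at_record <- rep(TRUE, n)
  if (!is.null(grid_step)) {
    grid <- seq(min(positions), max(positions), by = grid_step)
    grid <- setdiff(grid, positions)
    eval_pos <- c(eval_pos, grid)
    at_record <- c(at_record, rep(FALSE, length(grid)))
  }
  o2 <- order(eval_pos)
  eval_pos <- eval_pos[o2]; at_record <- at_record[o2]
  sm <- stats::predict(fit, newdata = data.frame(positions = eval_pos))
  structure(list(
    profile = data.frame(position = eval_pos, smoothed = as.numeric(sm),
                         at_record = at_record),
    span = span, degree = degree, chromosome = chromosome
  ), class = "scan_profile")
}

#' @export
print.scan_profile <- function(x, ...) {
  cat(sprintf(
    "<scan_profile> %s: %d evaluation points (span %.2f, degree %d)\n",
    x$chromosome, nrow(x$profile), x$span, x$degree))
  invisible(x)
}

#' Maximum of a smoothed profile within an interval
#'
#' @param profile a `scan_profile`.
#' @param from,to interval bounds in bp (defaults: whole profile).
#' @return the maximum smoothed value over evaluation points in the interval.
#' @export
profile_max <- function(profile, from = -Inf, to = Inf) {
  p <- profile$profile
  sel <- p$position >= from & p$position <= to
  if (!any(sel)) return(NA_real_)
  max(p$smoothed[sel])
}

#' Sister-RAD-site FST correlation diagnostic
#'
#' Two RAD sites flanking the same restriction cut site are tightly
#' physically linked, so a marker FST that reliably reflects drift and
#' selection in the region should be similar between them.  For each
#' minor-allele-count threshold n this diagnostic restricts the per-SNP
#' table to SNPs passing n, max-aggregates clipped FST per site, pairs
#' left/right sister sites, and reports the Pearson correlation across
#' pairs.
#'
#' @param tab a per-SNP table with columns pair_id, side, site_id, position,
#'   minor_allele_count and clipped `fst`.
#' @param n_range thresholds to evaluate (default 1:10).
#' @param min_pairs minimum number of complete pairs for a correlation to be
#'   reported (default 10; fewer gives NA).
#' @return a data frame with columns n, pair_count and r.
#' @export
sister_correlation <- function(tab, n_range = 1:10, min_pairs = 10L) {
  rows <- lapply(n_range, function(n) {
    sub <- tab[tab$minor_allele_count >= n, , drop = FALSE]
    ps <- aggregate_per_site(sub)
    left <- ps[ps$side == "left", c("pair_id", "fst")]
    right <- ps[ps$side == "right", c("pair_id", "fst")]
    m <- merge(left, right, by = "pair_id", suffixes = c("_l", "_r"))
    r <- if (nrow(m) >= min_pairs && stats::sd(m$fst_l) > 0 &&
             stats::sd(m$fst_r) > 0) {
      stats::cor(m$fst_l, m$fst_r)
    } else NA_real_
    data.frame(n = n, pair_count = nrow(m), r = r)
  })
  do.call(rbind, rows)
}
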