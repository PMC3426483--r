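# End-to-end driver: simulate (or ingest) -> genotype -> coverage gate ->
# per-position FST -> minor-allele gate(s) -> aggregate -> sweep / scan /
# sister diagnostic, with TSV outputs and a per-stage record-count log.

#' Pipeline configuration
#'
#' Composes the simulation, genotyping, filtering and scan settings with a
#' root seed.  Round-trips losslessly through YAML via
#' [write_pipeline_config()] / [read_pipeline_config()].
#'
#' @param sim a `sim_config`.
#' @param genotyping a `genotyping_config`.
#' @param filter a `filter_config`.
#' @param n_range thresholds for the sweep and diagnostic.
#' @param span,degree LOESS settings for the profiles.
#' @param profile_n thresholds at which to compute smoothed profiles.
#' @param estimator default per-SNP FST estimator.
#' @param aggregation per-site aggregation rule.
#' @param mode `"genotypes"` runs the fast genotype-level path (true
#'   simulated genotypes feed the FST stage directly); `"stacks"` runs the
#'   full read-stack path through consensus genotyping; `"ingest"` reads a
#'   genotype TSV from `ingest_path` instead of simulating.
#' @param ingest_path,pop_map_path inputs for `mode = "ingest"`.
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = sim_config(),
                            genotyping = genotyping_config(),
                            filter = filter_config(),
                            n_range = 1:10,
                            span = 0.4, degree = 2L,
                            profile_n = c(1L, 4L),
                            estimator = c("haplotype", "theta"),
                            aggregation = c("max", "mean", "random"),
                            mode = c("genotypes", "stacks", "ingest"),
                            ingest_path = NULL, pop_map_path = NULL) {
  structure(list(sim = sim, genotyping = genotyping, filter = filter,
                 n_range = as.integer(n_range), span = span,
                 degree = as.integer(degree),
                 profile_n = as.integer(profile_n),
                 estimator = match.arg(estimator),
                 aggregation = match.arg(aggregation),
                 mode = match.arg(mode),
                 ingest_path = ingest_path, pop_map_path = pop_map_path),
            class = "pipeline_config")
}

#' Write a pipeline configuration as YAML
#' @param config a `pipeline_config`.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_pipeline_config <- function(config, path) {
  plain <- lapply(config, function(x) if (is.list(x)) unclass(x) else x)
  yaml::write_yaml(plain, path)
  invisible(path)
}

#' Read a pipeline configuration from YAML
#' @param path a file written by [write_pipeline_config()].
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  sim <- do.call(sim_config, y$sim[!vapply(y$sim, is.null, logical(1))])
  gt <- do.call(genotyping_config, y$genotyping)
  fl <- do.call(filter_config, y$filter[!vapply(y$filter, is.null, logical(1))])
  pipeline_config(sim = sim, genotyping = gt, filter = fl,
                  n_range = y$n_range, span = y$span, degree = y$degree,
                  profile_n = y$profile_n, estimator = y$estimator,
                  aggregation = y$aggregation, mode = y$mode,
                  ingest_path = y$ingest_path, pop_map_path = y$pop_map_path)
}

# Flatten pooled snp_site lists (per RAD site) into the per-SNP table the
# sweep/scan stage consumes; optional annotations supply pair/side columns.
snp_sites_to_table <- function(pools, annotations = NULL) {
  rows <- list()
  for (site in names(pools)) {
    for (s in pools[[site]]) {
      g <- s$diploid_counts
      rows[[length(rows) + 1L]] <- data.frame(
        site_id = s$site_id, chromosome = s$chromosome,
        position = s$position,
        c1 = s$counts[1, 2], m1 = sum(s$counts[1, ]),
        c2 = s$counts[2, 2], m2 = sum(s$counts[2, ]),
        het1 = s$het_counts[1], het2 = s$het_counts[2],
        nAA1 = if (is.null(g)) NA_integer_ else g[1, 1],
        nAa1 = if (is.null(g)) NA_integer_ else g[1, 2],
        naa1 = if (is.null(g)) NA_integer_ else g[1, 3],
        nAA2 = if (is.null(g)) NA_integer_ else g[2, 1],
        nAa2 = if (is.null(g)) NA_integer_ else g[2, 2],
        naa2 = if (is.null(g)) NA_integer_ else g[2, 3],
        minor_allele_count = s$minor_allele_count,
        stringsAsFactors = FALSE)
    }
  }
  tab <- do.call(rbind, rows)
  if (!is.null(tab) && !is.null(annotations)) {
    hit <- match(tab$site_id, annotations$site_id)
    tab$side <- annotations$side[hit]
    tab$cut_position <- annotations$cut_position[hit]
    tab$pair_id <- match(tab$cut_position,
                         sort(unique(tab$cut_position)))
  }
  tab
}

#' Run the full genome-scan pipeline
#'
#' Executes the configured stages in order and, when `out_dir` is given,
#' writes every stage table as TSV (and the smoothed profiles as
#' BEDGRAPH-style exports).  Deterministic for a fixed seed.
#'
#' @param config a `pipeline_config`.
#' @param out_dir optional output directory.
#' @return a list with the simulation (if any), the per-SNP table with FST
#'   columns (`snps`), the filtered table (`snps_passing`), the per-site
#'   aggregated records at n = 1 (`sites`), the sweep summary (`sweep`),
#'   smoothed profiles per requested threshold (`profiles`), the sister
#'   diagnostic (`sister`, when pair information is present) and a
#'   per-stage record-count log (`log`).
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  log <- list()
  sim <- NULL
  annotations <- NULL
  if (config$mode == "ingest") {
    if (is.null(config$ingest_path) || is.null(config$pop_map_path))
      stop("stage ingest: ingest_path and pop_map_path are required")
    pools <- read_genotype_matrix(config$ingest_path, "tsv",
                                  config$pop_map_path)
    tab <- snp_sites_to_table(pools)
  } else {
    sim <- simulate_populations(config$sim)
    log$sites_simulated <- nrow(sim$sites)
    if (config$mode == "stacks") {
      stacks <- simulate_read_stacks(sim)
      genos <- genotype_stacks(stacks, config$genotyping)
      annotations <- sim$sites[, c("site_id", "chromosome", "cut_position",
                                   "side")]
      keep <- vapply(split_by_site(genos), coverage_gate, logical(1),
                     config = config$filter)
      log$sites_passing_coverage <- sum(keep)
      log$sites_failing_coverage <- sum(!keep)
      genos <- genos[vapply(genos, function(g)
        isTRUE(keep[[g$site_id]]), logical(1))]
      pools <- pool_genotypes(structure(genos, class = "genotype_set"),
                              annotations = annotations)
      tab <- snp_sites_to_table(pools, annotations = annotations)
    } else {
      tab <- sim_snp_table(sim)
    }
  }
  if (is.null(tab) || nrow(tab) == 0L) stop("stage fst: no variable positions")
  log$snps_screened <- nrow(tab)
  tab <- add_fst(tab, config$estimator)
  tab_pass <- apply_filters(tab, config$filter)
  log$filter <- attr(tab_pass, "filter_log")
  sites <- aggregate_per_site(tab_pass)
  log$sites_aggregated <- nrow(sites)
  sweep <- threshold_sweep(tab_pass, config$n_range)
  profiles <- list()
  for (n in config$profile_n) {
    sub <- aggregate_per_site(
      tab_pass[tab_pass$minor_allele_count >= n, , drop = FALSE])
    if (nrow(sub) >= 4L) {
      profiles[[as.character(n)]] <- loess_profile(
        sub$position, sub$fst, span = config$span, degree = config$degree,
        chromosome = sub$chromosome[1])
    }
  }
  sister <- NULL
  if (!is.null(tab_pass$pair_id) && !is.null(tab_pass$side) &&
      any(duplicated(tab_pass$pair_id)))
    sister <- sister_correlation(tab_pass, config$n_range)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_tsv(tab, file.path(out_dir, "snps.tsv"))
    write_tsv(sites, file.path(out_dir, "sites_fst.tsv"))
    write_tsv(sweep, file.path(out_dir, "sweep.tsv"))
    if (!is.null(sister)) write_tsv(sister, file.path(out_dir, "sister.tsv"))
    for (n in names(profiles))
      write_profile_bedgraph(profiles[[n]],
                             file.path(out_dir,
                                       sprintf("profile_n%s.bedgraph", n)))
    if (!is.null(sim)) {
      write_annotations(sim$sites, file.path(out_dir, "annotations.tsv"))
      write_tsv(sim$sites, file.path(out_dir, "sim_sites.tsv"))
    }
  }
  list(sim = sim, snps = tab, snps_passing = tab_pass, sites = sites,
       sweep = sweep, profiles = profiles, sister = sister, log = log)
}

split_by_site <- function(genos) {
  split(genos, vapply(genos, `[[`, character(1), "site_id"))
}
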