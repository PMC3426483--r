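# Readers and writers for the pipeline's on-disk formats: stack TSV,
# genotype TSV, RAD-site annotation TSV, genotype matrices (TSV or VCF),
# BEDGRAPH-style profile export and the YAML pipeline configuration.
# Internal coordinates are 1-based inclusive; BED-family exports are
# converted to 0-based half-open intervals.

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

read_tsv <- function(path, ...) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE, ...)
}

#' Write read stacks to the tab-delimited stack format
#'
#' One row per base: site_id, individual_id, population_id, read (1-based
#' read index), position (1-based offset within the read), base, error_prob.
#'
#' @param stacks a `stack_set`.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_stacks <- function(stacks, path) {
  rows <- lapply(stacks, function(s) {
    d <- nrow(s$bases); L <- ncol(s$bases)
    if (d == 0L) return(NULL)
    data.frame(site_id = s$site_id, individual_id = s$individual_id,
               population_id = s$population_id,
               read = rep(seq_len(d), L),
               position = rep(seq_len(L), each = d),
               base = as.vector(s$bases),
               error_prob = as.vector(s$error_probs),
               stringsAsFactors = FALSE)
  })
  write_tsv(do.call(rbind, rows), path)
}

#' Read the tab-delimited stack format
#'
#' @param path a file written by [write_stacks()].
#' @return a `stack_set`.
#' @export
read_stacks <- function(path) {
  df <- read_tsv(path, colClasses = c(base = "character"))
  key <- interaction(df$site_id, df$individual_id, drop = TRUE)
  out <- lapply(split(df, key), function(d) {
    dd <- max(d$read); L <- max(d$position)
    b <- matrix(NA_character_, dd, L)
    e <- matrix(NA_real_, dd, L)
    b[cbind(d$read, d$position)] <- d$base
    e[cbind(d$read, d$position)] <- d$error_prob
    read_stack(d$site_id[1], d$individual_id[1], d$population_id[1], b, e)
  })
  names(out) <- NULL
  structure(out, class = "stack_set")
}

#' Write consensus genotypes as TSV
#'
#' One row per individual x site x called position: site_id, individual_id,
#' population_id, ploidy, position, allele1, allele2 (NA for haploid calls).
#'
#' @param genotypes a `genotype_set`.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_genotypes <- function(genotypes, path) {
  rows <- lapply(genotypes, function(g) {
    pos <- which(colSums(!is.na(g$calls)) > 0L)
    if (!length(pos)) {
      # keep a row so all-missing individuals survive the round trip
      return(data.frame(site_id = g$site_id, individual_id = g$individual_id,
                        population_id = g$population_id, ploidy = g$ploidy,
                        n_positions = ncol(g$calls), position = NA_integer_,
                        allele1 = NA_character_, allele2 = NA_character_,
                        stringsAsFactors = FALSE))
    }
    data.frame(site_id = g$site_id, individual_id = g$individual_id,
               population_id = g$population_id, ploidy = g$ploidy,
               n_positions = ncol(g$calls), position = pos,
               allele1 = g$calls[1, pos],
               allele2 = if (g$ploidy == 2L) g$calls[2, pos]
                         else NA_character_,
               stringsAsFactors = FALSE)
  })
  write_tsv(do.call(rbind, rows), path)
}

#' Read a consensus genotype TSV
#'
#' @param path a file written by [write_genotypes()].
#' @return a `genotype_set`.
#' @export
read_genotypes <- function(path) {
  df <- read_tsv(path, colClasses = c(allele1 = "character",
                                      allele2 = "character"))
  key <- interaction(df$site_id, df$individual_id, drop = TRUE)
  out <- lapply(split(df, key), function(d) {
    L <- d$n_positions[1]; pl <- d$ploidy[1]
    calls <- matrix(NA_character_, pl, L)
    d <- d[!is.na(d$position), , drop = FALSE]
    if (nrow(d)) {
      calls[1, d$position] <- d$allele1
      if (pl == 2L) calls[2, d$position] <- d$allele2
    }
    structure(list(site_id = d$site_id[1] %||% NA, individual_id =
                     d$individual_id[1], population_id = d$population_id[1],
                   ploidy = pl, depth = NA_integer_, calls = calls),
              class = "consensus_genotype")
  })
  # restore identifiers for all-missing individuals dropped by subsetting
  ids <- split(df, key)
  for (i in seq_along(out)) {
    out[[i]]$site_id <- ids[[i]]$site_id[1]
    out[[i]]$individual_id <- ids[[i]]$individual_id[1]
    out[[i]]$population_id <- ids[[i]]$population_id[1]
  }
  names(out) <- NULL
  structure(out, class = "genotype_set")
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0L || is.na(a[1])) b else a

#' Write RAD-site annotations
#'
#' BED-like TSV with 1-based inclusive cut positions: site_id, chromosome,
#' cut_position, side.
#'
#' @param annotations data frame with those columns.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_annotations <- function(annotations, path) {
  write_tsv(annotations[, c("site_id", "chromosome", "cut_position", "side")],
            path)
}

#' Read RAD-site annotations
#' @param path a file written by [write_annotations()].
#' @return a data frame.
#' @export
read_annotations <- function(path) read_tsv(path)

#' Read a pre-called genotype matrix
#'
#' Ingests genotypes from either the pipeline's genotype TSV or a VCF with
#' GT fields, assigns populations from a sample-to-population map, and pools
#' them into per-position SNP records.  Haploid calls (single-allele GT) are
#' supported; missing genotypes stay missing.
#'
#' @param path input file.
#' @param dialect `"tsv"` or `"vcf"`.
#' @param pop_map a data frame with columns `sample` and `population`, or
#'   the path of a TSV with those columns.  Every sample in the input must
#'   appear in the map; an unknown sample is an error naming it.
#' @return for `"tsv"`: a named list (per RAD site) of `snp_site` lists, as
#'   from [pool_genotypes()]; for `"vcf"`: a list of `snp_site` objects, one
#'   per biallelic VCF record.
#' @export
read_genotype_matrix <- function(path, dialect = c("tsv", "vcf"), pop_map) {
  dialect <- match.arg(dialect)
  if (is.character(pop_map)) pop_map <- read_tsv(pop_map)
  stopifnot(all(c("sample", "population") %in% names(pop_map)))
  pops <- sort(unique(pop_map$population))
  if (length(pops) != 2L) stop("population map must define exactly two populations")
  if (dialect == "tsv") {
    genos <- read_genotypes(path)
    for (i in seq_along(genos)) {
      id <- genos[[i]]$individual_id
      hit <- match(id, pop_map$sample)
      if (is.na(hit)) stop("sample not in population map: ", id)
      genos[[i]]$population_id <- pop_map$population[hit]
    }
    return(pool_genotypes(genos, populations = pops))
  }
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(vcf, element = "GT")
  fix <- vcfR::getFIX(vcf)
  samples <- colnames(gt)
  hit <- match(samples, pop_map$sample)
  if (anyNA(hit))
    stop("sample not in population map: ", samples[which(is.na(hit))[1]])
  sample_pop <- pop_map$population[hit]
  out <- list()
  for (i in seq_len(nrow(gt))) {
    ref <- fix[i, "REF"]; alt <- fix[i, "ALT"]
    if (is.na(alt) || nchar(ref) != 1L || nchar(alt) != 1L) next
    counts <- matrix(0L, 2L, 2L, dimnames = list(pops, c(ref, alt)))
    het <- c(0L, 0L); dip <- matrix(0L, 2L, 3L)
    for (j in seq_along(samples)) {
      g <- gt[i, j]
      if (is.na(g) || g %in% c(".", "./.", ".|.")) next
      al <- suppressWarnings(as.integer(strsplit(g, "[/|]")[[1]]))
      al <- al[!is.na(al)]
      if (!length(al)) next
      pi <- match(sample_pop[j], pops)
      counts[pi, 1] <- counts[pi, 1] + sum(al == 0L)
      counts[pi, 2] <- counts[pi, 2] + sum(al == 1L)
      if (length(al) == 2L) {
        nalt <- sum(al == 1L)
        dip[pi, nalt + 1L] <- dip[pi, nalt + 1L] + 1L
        if (nalt == 1L) het[pi] <- het[pi] + 1L
      }
    }
    if (sum(counts[, 2]) < 1L || sum(counts[, 1]) < 1L) next
    alleles <- c(ref, alt)
    if (sum(counts[, 2]) > sum(counts[, 1])) {
      counts <- counts[, 2:1]
      alleles <- rev(alleles)
      dip <- dip[, 3:1]
    }
    out[[length(out) + 1L]] <- snp_site(
      chromosome = fix[i, "CHROM"],
      position = as.integer(fix[i, "POS"]),
      site_id = if (!is.na(fix[i, "ID"]) && fix[i, "ID"] != ".")
        fix[i, "ID"] else paste0(fix[i, "CHROM"], ":", fix[i, "POS"]),
      alleles = alleles, counts = counts, het_counts = het,
      diploid_counts = dip)
  }
  out
}

#' Export a smoothed profile as BEDGRAPH-style TSV
#'
#' Columns chromosome, start, end, fst with 0-based half-open intervals
#' (each evaluation point becomes a 1-bp interval).
#'
#' @param profile a `scan_profile`.
#' @param path output path.
#' @param grid_only export only the uniform-grid evaluation points.
#' @return the path, invisibly.
#' @export
write_profile_bedgraph <- function(profile, path, grid_only = FALSE) {
  p <- profile$profile
  if (grid_only) p <- p[!p$at_record, , drop = FALSE]
  write_tsv(data.frame(chromosome = profile$chromosome,
                       start = p$position - 1L, end = p$position,
                       fst = p$smoothed), path)
}

#' Read a BEDGRAPH-style profile export
#' @param path a file written by [write_profile_bedgraph()].
#' @return a data frame with 1-based `position` and `smoothed` columns.
#' @export
read_profile_bedgraph <- function(path) {
  df <- read_tsv(path)
  data.frame(chromosome = df$chromosome, position = df$start + 1L,
             smoothed = df$fst)
}
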