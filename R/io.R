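#' Read a long-format probe intensity table
#'
#' One row per probe reading (probe x hybridisation x channel). Canonical
#' columns: `probe_id`, `gene_id` (empty/NA for anonymous clones),
#' `array_id`, `block_id`, `dye`, `foreground`, `background`, `snr`.
#' GenePix-style exports can be adapted with `column_map`, a named character
#' vector `c(canonical = "file column")`.
#'
#' @param path Path to a tab-separated file with a header.
#' @param column_map Optional renaming map, e.g.
#'   `c(foreground = "F635 Median", background = "B635 Median")`.
#' @return Data frame with the canonical columns.
#' @export
read_intensity_table <- function(path, column_map = NULL) {
  x <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!is.null(column_map)) {
    for (canon in names(column_map)) {
      src <- column_map[[canon]]
      if (!src %in% names(x))
        .stopf("column '%s' (mapped to '%s') not found in %s", src, canon, path)
      names(x)[names(x) == src] <- canon
    }
  }
  need <- c("probe_id", "array_id", "dye", "foreground", "background", "snr")
  miss <- setdiff(need, names(x))
  if (length(miss))
    .stopf("intensity table %s is missing column(s): %s", path,
           paste(miss, collapse = ", "))
  if (any(x$foreground < 0, na.rm = TRUE) || any(x$snr < 0, na.rm = TRUE))
    .stopf("foreground and SNR must be >= 0")
  x
}

#' Drop probes undetectable in every hybridisation
#'
#' A probe is retained iff its signal-to-noise ratio is at least 1 in at
#' least one hybridisation/channel; probes below 1 everywhere are deemed
#' undetectable and removed.
#'
#' @param probes Long-format probe table (see [read_intensity_table()]).
#' @return The table restricted to detectable probes, with attribute
#'   `n_removed` giving the count of dropped probes.
#' @export
filter_undetectable <- function(probes) {
  if (nrow(probes) == 0L) {
    .warnf("empty probe table: nothing to filter")
    return(structure(probes, n_removed = 0L))
  }
  max_snr <- tapply(probes$snr, probes$probe_id, max, na.rm = TRUE)
  keep <- names(max_snr)[max_snr >= 1]
  out <- probes[probes$probe_id %in% keep, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, n_removed = length(max_snr) - length(keep))
}

#' Collapse multi-probe genes to their most abundant probe
#'
#' For genes represented by more than one probe, keeps the probe with the
#' highest background-corrected intensity averaged over all hybridisations
#' and channels (abundant probes are better annotated and less noisy); ties
#' are broken by the lexicographically smallest probe id. Anonymous probes
#' (missing `gene_id`) pass through as their own gene.
#'
#' @param probes Long-format probe table.
#' @return The table restricted to one probe per gene, with `gene_id` filled
#'   in for anonymous probes.
#' @export
collapse_probes_to_genes <- function(probes) {
  if (nrow(probes) == 0L) return(probes)
  anon <- is.na(probes$gene_id) | probes$gene_id == ""
  probes$gene_id[anon] <- probes$probe_id[anon]
  net <- probes$foreground - probes$background
  mean_by_probe <- tapply(net, probes$probe_id, mean, na.rm = TRUE)
  info <- unique(probes[, c("probe_id", "gene_id")])
  info$mean_net <- mean_by_probe[info$probe_id]
  info <- info[order(info$gene_id, -info$mean_net, info$probe_id), ]
  keep <- info$probe_id[!duplicated(info$gene_id)]
  out <- probes[probes$probe_id %in% keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Convert edited probe readings to analysis-ready observations
#'
#' Background-corrects each reading by simple subtraction and log2-transforms
#' it; readings with foreground at or below background are dropped (and
#' counted) rather than floored. The sample sheet maps each (array, dye)
#' channel to the flock and treatment of the RNA sample it carried.
#'
#' @param probes Edited probe table ([filter_undetectable()] then
#'   [collapse_probes_to_genes()]).
#' @param design Sample sheet: data frame with columns `array_id`, `dye`,
#'   `flock_id`, `treatment_id`.
#' @return Observation data frame (`array_id`, `block_id`, `dye`, `gene_id`,
#'   `flock_id`, `treatment_id`, `log2_intensity`) with attribute
#'   `n_dropped` (non-positive net intensities).
#' @export
to_observations <- function(probes, design) {
  need <- c("array_id", "dye", "flock_id", "treatment_id")
  miss <- setdiff(need, names(design))
  if (length(miss))
    .stopf("sample sheet is missing column(s): %s", paste(miss, collapse = ", "))
  key_obs <- paste(probes$array_id, probes$dye, sep = ":")
  key_des <- paste(design$array_id, design$dye, sep = ":")
  if (anyDuplicated(key_des))
    .stopf("design error: duplicated (array, dye) entries in sample sheet")
  idx <- match(key_obs, key_des)
  if (anyNA(idx)) {
    bad <- unique(key_obs[is.na(idx)])
    .stopf("design error: (array, dye) pair(s) missing from sample sheet: %s",
           paste(head(bad, 5L), collapse = ", "))
  }
  net <- probes$foreground - probes$background
  ok <- is.finite(net) & net > 0
  n_dropped <- sum(!ok)
  probes <- probes[ok, , drop = FALSE]
  idx <- idx[ok]
  out <- data.frame(
    array_id = probes$array_id,
    block_id = if ("block_id" %in% names(probes)) probes$block_id else 1L,
    dye = probes$dye,
    gene_id = probes$gene_id,
    flock_id = design$flock_id[idx],
    treatment_id = design$treatment_id[idx],
    log2_intensity = log2(net[ok]),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  structure(out, n_dropped = n_dropped)
}

#' @rdname read_tables
#' @export
read_pedigree <- function(path) {
  x <- read.delim(path, stringsAsFactors = FALSE,
                  colClasses = "character")
  need <- c("animal", "sire", "dam")
  miss <- setdiff(need, names(x))
  if (length(miss)) .stopf("pedigree is missing column(s): %s",
                           paste(miss, collapse = ", "))
  for (col in c("sire", "dam"))
    x[[col]][x[[col]] %in% c("0", "", "NA")] <- NA_character_
  x
}

#' Readers and writers for the pipeline's tab-separated tables
#'
#' All tables are plain TSV with a header. Pedigrees use `0`/`NA`/empty for
#' unknown parents. Genotype tables are animal-by-SNP with calls either as
#' allele pairs (`"A/B"`) or as numeric dosages 0/1/2; allele pairs are
#' converted to minor-allele dosage per SNP. Tables round-trip through
#' [write_table_tsv()] unchanged.
#'
#' @param path File path.
#' @return A data frame ([read_phenotypes()], [read_pedigree()],
#'   [read_annotation()], [read_sample_sheet()]) or a numeric animal x SNP
#'   dosage matrix ([read_genotypes()]).
#' @name read_tables
#' @export
read_phenotypes <- function(path) {
  read.delim(path, stringsAsFactors = FALSE)
}

#' @rdname read_tables
#' @export
read_sample_sheet <- function(path) {
  read.delim(path, stringsAsFactors = FALSE)
}

#' @rdname read_tables
#' @export
read_annotation <- function(path) {
  x <- read.delim(path, stringsAsFactors = FALSE)
  miss <- setdiff(c("gene_id", "term_id"), names(x))
  if (length(miss)) .stopf("annotation is missing column(s): %s",
                           paste(miss, collapse = ", "))
  if (!"term_name" %in% names(x)) x$term_name <- x$term_id
  x
}

#' @rdname read_tables
#' @export
read_genotypes <- function(path) {
  x <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!"animal" %in% names(x)) .stopf("genotype table needs an 'animal' column")
  animals <- x$animal
  x$animal <- NULL
  geno <- matrix(NA_real_, length(animals), ncol(x),
                 dimnames = list(animals, names(x)))
  for (j in seq_along(x)) {
    v <- x[[j]]
    if (is.numeric(v)) {
      if (any(!v %in% c(0, 1, 2) & !is.na(v)))
        .stopf("dosages for SNP '%s' must be 0/1/2 or NA", names(x)[j])
      geno[, j] <- v
    } else {
      v[v %in% c("", "NA", "./.")] <- NA_character_
      pairs <- strsplit(v, "/", fixed = TRUE)
      ok <- !vapply(pairs, function(p) any(is.na(p)) || length(p) != 2L,
                    logical(1L))
      alle <- unlist(pairs[ok])
      if (!length(alle)) next
      tab <- table(alle)
      if (length(tab) == 1L) {
        # monomorphic: the minor allele is absent, every dosage is 0
        geno[ok, j] <- 0
        next
      }
      counts <- sort(tab, decreasing = TRUE)
      # count the rarer allele; exact ties count the alphabetically later one
      minor <- names(counts)[length(counts)]
      geno[ok, j] <- vapply(pairs[ok], function(p) sum(p == minor), numeric(1L))
    }
  }
  geno
}

#' Write a pipeline table as TSV
#'
#' @param x Data frame (or matrix with row names, written with an `animal`
#'   key column).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_table_tsv <- function(x, path) {
  if (is.matrix(x))
    x <- data.frame(animal = rownames(x), x, check.names = FALSE,
                    stringsAsFactors = FALSE)
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
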