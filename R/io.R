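#' Read and write the canonical plain-text data formats
#'
#' Genotypes: tab-delimited dosage matrix, header row of SNP ids, first
#' column `id`. Phenotypes: tab-delimited table with columns id, generation,
#' role, pheno_A, pheno_B, tbv_A, tbv_B, liability_B. QTL truth: tab-delimited
#' (locus, group, a_A, a_B). Scenario configs are JSON.
#'
#' @param x Object to write (matrix or data frame as appropriate).
#' @param path File path.
#' @return Readers return the object; writers return `path` invisibly.
#' @name ltbc_io
NULL

#' @rdname ltbc_io
#' @export
write_dosage <- function(x, path) {
  df <- data.frame(id = rownames(x), x, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname ltbc_io
#' @export
read_dosage <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "integer"
  rownames(m) <- df$id
  m
}

#' @rdname ltbc_io
#' @export
write_phenotypes <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname ltbc_io
#' @export
read_phenotypes <- function(path) {
  need <- c("id", "generation", "role")
  df <- utils::read.delim(path, check.names = FALSE)
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("phenotype file lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  tibble::as_tibble(df)
}

#' @rdname ltbc_io
#' @export
write_qtl <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname ltbc_io
#' @export
read_qtl <- function(path) tibble::as_tibble(utils::read.delim(path))

#' Write or read a simulation scenario configuration
#'
#' A JSON container holding genome, demography and architecture settings plus
#' the seed and replicate index, so a replicate can be reproduced exactly.
#'
#' @param genome,demography,architecture Configuration objects.
#' @param seed,replicate Integers.
#' @param path File path.
#' @return `read_scenario_config()` returns a list with re-built
#'   configuration objects.
#' @export
write_scenario_config <- function(genome, demography, architecture,
                                  seed, replicate, path) {
  strip <- function(x, drop) {
    x <- unclass(x)
    x[setdiff(names(x), drop)]
  }
  obj <- list(
    genome = strip(genome, c("loci", "rec")),
    demography = unclass(demography),
    architecture = unclass(architecture),
    seed = seed, replicate = replicate)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_scenario_config
#' @export
read_scenario_config <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  list(
    genome = do.call(genome_config, obj$genome),
    demography = do.call(demography_config, obj$demography),
    architecture = do.call(architecture_config, obj$architecture),
    seed = obj$seed, replicate = obj$replicate)
}
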