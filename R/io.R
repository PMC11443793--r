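# GAMETES-style dataset files: tab-delimited UTF-8 text, one header row of
# feature names (predictive loci carry M<model>P<locus> names, non-predictive
# loci N<i>), final column "Class" in {0,1}, integer genotypes in {0,1,2}.

#' Write a genotype dataset to a GAMETES-style TSV file
#'
#' @param dataset A `genotype_dataset`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(dataset, path) {
  validate_dataset(dataset)
  dt <- data.table::as.data.table(dataset$genotypes)
  data.table::setnames(dt, colnames(dataset$genotypes))
  data.table::set(dt, j = "Class", value = dataset$labels)
  data.table::fwrite(dt, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' Read a GAMETES-style TSV dataset file
#'
#' Predictive features are recognized by their `M<model>P<locus>` column
#' names; any cell outside `{0,1,2}` (or a label outside `{0,1}`, or a
#' missing final `Class` column) raises a format error naming the offending
#' row and column.
#'
#' @param path Path to a tab-delimited dataset file.
#' @param config_id,replicate_seed Optional metadata to attach.
#' @return A `genotype_dataset`.
#' @export
read_dataset <- function(path, config_id = NA_character_, replicate_seed = NULL) {
  if (!file.exists(path)) abort_format(sprintf("no such dataset file: %s", path))
  dt <- data.table::fread(path, sep = "\t", header = TRUE, colClasses = "numeric")
  nms <- names(dt)
  if (nms[length(nms)] != "Class") {
    abort_format("final column must be named 'Class'")
  }
  y <- dt[["Class"]]
  X <- as.matrix(dt)[, setdiff(nms, "Class"), drop = FALSE]
  bad <- which(!(X %in% 0:2) | X != floor(X))
  if (length(bad)) {
    rc <- arrayInd(bad[1L], dim(X))
    abort_format(sprintf("invalid genotype value %s at row %d, column '%s'",
                         format(X[bad[1L]]), rc[1L], colnames(X)[rc[2L]]))
  }
  if (!all(y %in% 0:1)) {
    abort_format(sprintf("invalid Class value at row %d",
                         which(!(y %in% 0:1))[1L]))
  }
  pred <- grep("^M[0-9]+P[0-9]+$", colnames(X))
  if (length(pred) == 0L) {
    abort_format("no predictive (M<i>P<j>-named) feature columns found")
  }
  storage.mode(X) <- "integer"
  new_genotype_dataset(X, as.integer(y), predictive_idx = pred,
                       config_id = config_id, replicate_seed = replicate_seed)
}
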