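#' Read and write labelled spectra as wide CSV
#'
#' The on-disk format is one row per sample with a header
#' `sample_id,label,f_0.5000,...,f_0.9000`, frequencies in THz printed to
#' four decimals.
#'
#' @param x a [ThzSpectra-class].
#' @param path CSV file path.
#' @return `writeSpectraCsv` invisibly returns `path`; `readSpectraCsv`
#'   returns a [ThzSpectra-class].
#' @export
writeSpectraCsv <- function(x, path) {
  stopifnot(is(x, "ThzSpectra"))
  K <- kappaMatrix(x)
  colnames(K) <- sprintf("f_%.4f", frequencyGrid(x))
  df <- data.frame(sample_id = colnames(x),
                   label = as.integer(classLabels(x)),
                   K, check.names = FALSE, row.names = NULL)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeSpectraCsv
#' @export
readSpectraCsv <- function(path) {
  df <- read.csv(path, check.names = FALSE)
  fcols <- grep("^f_", names(df), value = TRUE)
  freqs <- as.numeric(sub("^f_", "", fcols))
  # header frequencies are printed to 4 decimals; snap back to the uniform grid
  uni <- seq(freqs[1], freqs[length(freqs)], length.out = length(freqs))
  if (max(abs(uni - freqs)) < 1e-3) freqs <- uni
  ThzSpectra(t(as.matrix(df[, fcols])), freqs,
             labels = df$label, sampleIds = as.character(df$sample_id))
}

#' Write a time-domain trace as two-column CSV
#'
#' @param trace `data.frame(time_ps, amplitude)`.
#' @param path CSV file path.
#' @export
writeTraceCsv <- function(trace, path) {
  write.csv(trace[, c("time_ps", "amplitude")], path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeTraceCsv
#' @export
readTraceCsv <- function(path) read.csv(path)
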