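#' Write a schedule (and optional responses) as a BIDS-style events table
#'
#' Tab-separated with columns `onset`, `duration`, `trial_type`,
#' `sample_1..3`, `loc_1..3`, `probed_index`, and, when responses are
#' given, `response` and `error`.
#'
#' @param schedule a `trial_schedule`.
#' @param path output file.
#' @param responses optional `response_table` aligned by trial.
#' @export
write_events_tsv <- function(schedule, path, responses = NULL) {
  out <- data.frame(onset = schedule$onset_sample,
                    duration = 4,
                    trial_type = schedule$condition,
                    sample_1 = schedule$sample_1,
                    sample_2 = schedule$sample_2,
                    sample_3 = schedule$sample_3,
                    loc_1 = schedule$loc_1,
                    loc_2 = schedule$loc_2,
                    loc_3 = schedule$loc_3,
                    probed_index = schedule$probed_index)
  if (!is.null(responses)) {
    out$response <- responses$response
    out$error <- responses$error
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "n/a")
  invisible(path)
}

#' Read a BIDS-style events table
#' @param path events TSV written by [write_events_tsv()] or compatible.
#' @return a `data.frame`.
#' @export
read_events_tsv <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", na.strings = "n/a",
                    stringsAsFactors = FALSE)
}

#' Write a CTF as a two-column TSV (offset, response)
#' @param ctf a `ctf` object.
#' @param path output file.
#' @export
write_ctf_tsv <- function(ctf, path) {
  utils::write.table(data.frame(offset = ctf$offsets, response = ctf$values),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Serialize a model fit (mixture or CTF) to JSON
#' @param fit a `mixture_fit`, `ctf_fit`, or `bootstrap_result`.
#' @param path output file.
#' @export
write_fit_json <- function(fit, path) {
  x <- unclass(fit)
  x$loglik_trace <- NULL; x$x_rad <- NULL; x$y <- NULL; x$fitted <- NULL
  x$values <- NULL
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Export a voxel dataset as NIfTI (voxels unraveled onto a dummy grid)
#'
#' Voxels are laid out along a dummy 3-D grid with TR as the 4th dimension.
#' Requires the `RNifti` package.
#'
#' @param dataset a `voxel_dataset`.
#' @param path output `.nii` file.
#' @export
export_nifti <- function(dataset, path) {
  if (!requireNamespace("RNifti", quietly = TRUE)) {
    stop("NIfTI export requires the RNifti package")
  }
  v <- nrow(dataset$signal); n_tr <- ncol(dataset$signal)
  dim1 <- ceiling(sqrt(v))
  dim2 <- ceiling(v / dim1)
  arr <- array(0, c(dim1, dim2, 1, n_tr))
  for (t in seq_len(n_tr)) {
    a <- numeric(dim1 * dim2)
    a[seq_len(v)] <- dataset$signal[, t]
    arr[, , 1, t] <- a
  }
  RNifti::writeNifti(RNifti::asNifti(arr, pixdim = c(1, 1, 1, 2)), path)
  invisible(path)
}

# lightweight run log: every generator call records its seed and parameters
.ctxbind_log <- new.env(parent = emptyenv())
.ctxbind_log$entries <- list()

log_call <- function(what, params) {
  .ctxbind_log$entries[[length(.ctxbind_log$entries) + 1]] <-
    list(time = format(Sys.time()), what = what, params = params)
  invisible(NULL)
}

#' Retrieve (or clear) the generator run log
#'
#' Every schedule, behavior and voxel simulation call appends its seed and
#' parameter set here, so a run's provenance can be serialized with its
#' outputs.
#'
#' @param clear if TRUE, empty the log after returning it.
#' @return list of log entries.
#' @export
run_log <- function(clear = FALSE) {
  out <- .ctxbind_log$entries
  if (clear) .ctxbind_log$entries <- list()
  out
}
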