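# Dataset and result readers/writers. The dataset CSV contract:
# patient_id,cluster_id,z,x,y0,y1,w0,w1[,u,y1_po_1,y1_po_0]; the oracle
# columns (unmeasured confounder and potential outcomes) are written only on
# request and are never consumed by any estimator.

.required_cols <- c("patient_id", "cluster_id", "z", "x", "y0", "y1",
                    "w0", "w1")
.oracle_cols <- c("u", "y1_po_1", "y1_po_0")

#' Write an analytic dataset to CSV
#'
#' @param data Dataset (e.g. from [simulate_dataset()]).
#' @param path Output CSV path.
#' @param oracle Also write the oracle-only columns (`u`, `y1_po_1`,
#'   `y1_po_0`) when present.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(data, path, oracle = FALSE) {
  require_columns(data, .required_cols)
  cols <- c(.required_cols,
            if (oracle) intersect(.oracle_cols, names(data)))
  write.csv(data[cols], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and validate an analytic dataset CSV
#'
#' Enforces the column contract: binary columns must be 0/1 and the
#' instrument must be constant within each cluster. Oracle columns are loaded
#' when present but are not used by any estimator.
#'
#' @param path CSV path.
#' @return Validated data.frame.
#' @export
read_dataset <- function(path) {
  data <- read.csv(path)
  require_columns(data, .required_cols)
  for (col in c("z", "x", "y0", "y1")) {
    bad <- which(!data[[col]] %in% c(0L, 1L))
    if (length(bad)) {
      validation_error("column '", col, "' is not binary 0/1 at row ", bad[1])
    }
  }
  split_z <- split(data$z, data$cluster_id)
  n_per <- vapply(split_z, function(zz) length(unique(zz)), integer(1))
  if (any(n_per > 1L)) {
    validation_error("instrument z varies within cluster ",
                     names(split_z)[which(n_per > 1L)[1]],
                     "; z must be constant per cluster")
  }
  data
}

#' Write effect estimates as JSON
#'
#' Serializes one or several `effect_estimate` objects to the result schema
#' `{method, beta_hat, se, ci, p_value, n_used, diagnostics}`.
#'
#' @param estimates An `effect_estimate` or a list of them.
#' @param path Output path; `NULL` returns the JSON string.
#' @return The JSON string, invisibly when written to a file.
#' @export
write_estimates_json <- function(estimates, path = NULL) {
  if (inherits(estimates, "effect_estimate")) estimates <- list(estimates)
  recs <- lapply(estimates, function(e) {
    list(method = e$method, beta_hat = e$beta_hat, se = e$se,
         ci = c(e$ci_low, e$ci_high), p_value = e$p_value,
         n_used = e$n_used,
         diagnostics = e$diagnostics[!vapply(e$diagnostics, is.null, logical(1))])
  })
  js <- jsonlite::toJSON(recs, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}

#' Write a dissimilarity result as JSON
#'
#' @param result A `dissimilarity_result`.
#' @param path Output path; `NULL` returns the JSON string.
#' @param replicates_path Optional CSV path for the bootstrap replicate
#'   matrix (requires `keep_replicates = TRUE` upstream).
#' @return The JSON string, invisibly when written to a file.
#' @export
write_dissimilarity_json <- function(result, path = NULL,
                                     replicates_path = NULL) {
  stopifnot(inherits(result, "dissimilarity_result"))
  obj <- list(
    methods = result$methods,
    beta_vec = as.numeric(result$beta_vec),
    ivw = result$ivw,
    cov = unname(apply(result$cov, 1, as.numeric, simplify = FALSE)),
    q_stat = result$q_stat, df = result$df, p_value = result$p_value,
    alpha = result$alpha, reject = result$reject,
    B = result$B, seed = result$seed,
    failed_resamples = result$failed_resamples
  )
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(replicates_path)) {
    reps <- attr(result, "replicates")
    if (is.null(reps)) {
      validation_error("result carries no replicate matrix; rerun with ",
                       "keep_replicates = TRUE")
    }
    write.csv(as.data.frame(reps), replicates_path, row.names = FALSE)
  }
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}
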