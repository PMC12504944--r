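# Deterministic hand-laid datasets for closed-form checks. The instrument is
# made cluster-constant by assigning one cluster per instrument level.
make_manual_dataset <- function(z, x, y0, y1, w0 = NULL, w1 = NULL) {
  n <- length(x)
  data.frame(
    patient_id = seq_len(n),
    cluster_id = z + 1L,
    z = z, x = x, y0 = y0, y1 = y1,
    w0 = if (is.null(w0)) seq(-1, 1, length.out = n) else w0,
    w1 = if (is.null(w1)) seq(1, -1, length.out = n) else w1
  )
}

# n per arm with a fixed number of events, laid out deterministically
binary_vec <- function(n, n_ones) rep(c(1L, 0L), c(n_ones, n - n_ones))

small_config <- function(id = "base1", n = 1000L, ...) {
  make_scenario_config(id, list(n = n, ...))
}
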