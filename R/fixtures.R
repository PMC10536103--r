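#' Embedded reference tables
#'
#' The package ships three small plain-text tables describing the
#' 12-proteinoid reference cohort and the 10-neuron model:
#' \describe{
#'   \item{`load_initial_weights()`}{the printed 10 x 10 initial synaptic
#'     weight matrix of the temporal-coding network (entries in
#'     \[-1, 1\]).}
#'   \item{`load_spike_characteristics()`}{per-proteinoid spike count,
#'     mean interspike interval (s) and spiking frequency (mHz), measured
#'     with a 0.0005 microampere threshold and 5 s minimum peak distance.}
#'   \item{`load_firing_rates()`}{per-sample mean firing rate (Hz) and
#'     the tabulated QSAR-predicted rate (Hz).}
#' }
#' `load_fixtures()` returns all three in one list.
#'
#' @return `load_initial_weights()`: a 10 x 10 numeric matrix.
#'   `load_spike_characteristics()`: a 12-row `data.frame` with columns
#'   `proteinoid`, `n_spikes`, `mean_isi_s`, `frequency_mhz`.
#'   `load_firing_rates()`: a 12-row `data.frame` with columns `sample`,
#'   `mean_firing_rate_hz`, `predicted_qsar_hz`.
#' @examples
#' dim(load_initial_weights())
#' nrow(load_spike_characteristics())
#' @export
load_initial_weights <- function() {
  path <- system.file("extdata", "initial_weights_10x10.csv",
                      package = "protospike", mustWork = TRUE)
  W <- as.matrix(utils::read.csv(path, header = FALSE))
  dimnames(W) <- NULL
  stopifnot(all(dim(W) == c(10L, 10L)), all(abs(W) <= 1))
  W
}

#' @rdname load_initial_weights
#' @export
load_spike_characteristics <- function() {
  path <- system.file("extdata", "spike_characteristics.csv",
                      package = "protospike", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' @rdname load_initial_weights
#' @export
load_firing_rates <- function() {
  path <- system.file("extdata", "firing_rates_qsar.csv",
                      package = "protospike", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' @rdname load_initial_weights
#' @export
load_fixtures <- function() {
  list(initial_weights = load_initial_weights(),
       spike_characteristics = load_spike_characteristics(),
       firing_rates = load_firing_rates())
}
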