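#' Population labels of the CCTC loop model
#'
#' The seven neural populations of the cortico-cerebello-thalamo-cortical
#' circuit, in canonical order: cerebral cortex (`CTX`), ventralis intermedius
#' thalamus (`VIM`), reticular thalamic nucleus (`NRT`), deep cerebellar
#' nuclei (`DCN`), subthalamic nucleus (`STN`), and the external and internal
#' globus pallidus (`GPE`, `GPI`).
#'
#' @return A character vector of length 7.
#' @export
#' @examples
#' cctc_populations()
cctc_populations <- function() {
  c("CTX", "VIM", "NRT", "DCN", "STN", "GPE", "GPI")
}

# populations whose efferent weights must be non-negative (excitatory) or
# non-positive (inhibitory)
.excitatory <- c("CTX", "VIM", "DCN", "STN")
.inhibitory <- c("NRT", "GPE", "GPI")

#' Load model parameters for the CCTC loop
#'
#' Reads a versioned YAML parameter file describing the seven-population rate
#' model: per-population time constants, logistic transfer parameters,
#' background drives, the signed connection list, reference firing rates and
#' the stimulation gain. The default file shipped with the package is
#' calibrated so the unforced deep-cerebellar-nuclei rate is 56.6 spikes/s
#' and a constant 2 mA-equivalent DCN drive produces gamma-band cortical
#' oscillations.
#'
#' @param file Path to a parameter YAML file. Defaults to the file shipped in
#'   `inst/extdata/cctc_params.yaml`.
#' @return An object of class `cctc_parameters`: a list with elements
#'   `populations` (tibble of per-population constants), `W` (7 x 7 signed
#'   weight matrix, entry `[i, j]` is the gain from population i to j),
#'   `background` (named numeric), `reference_rates`, and `stimulation`
#'   (`dcn_gain_per_mA`, `tdcs_reference_mA`).
#' @export
#' @examples
#' p <- cctc_parameters()
#' p$reference_rates$dcn_baseline
cctc_parameters <- function(file = NULL) {
  if (is.null(file)) {
    file <- system.file("extdata", "cctc_params.yaml", package = "cctcsim",
                        mustWork = TRUE)
  }
  raw <- yaml::read_yaml(file)
  pops <- cctc_populations()
  if (!setequal(names(raw$populations), pops)) {
    abort("parameter file must define exactly the populations CTX, VIM, NRT, DCN, STN, GPE, GPI",
          class = "cctcsim_parameter_error")
  }
  tab <- purrr::map_dfr(pops, function(nm) {
    p <- raw$populations[[nm]]
    tibble(population = nm, tau = p$tau, max_rate = p$max_rate,
           slope = p$slope, threshold = p$threshold,
           background = p$background)
  })
  W <- matrix(0, 7, 7, dimnames = list(pops, pops))
  for (e in raw$connections) {
    if (!e$from %in% pops || !e$to %in% pops) {
      abort(sprintf("connection %s -> %s names an unknown population", e$from, e$to),
            class = "cctcsim_parameter_error")
    }
    W[e$from, e$to] <- e$weight
  }
  out <- structure(
    list(populations = tab, W = W,
         background = stats::setNames(tab$background, tab$population),
         reference_rates = raw$reference_rates,
         stimulation = raw$stimulation,
         version = raw$version, file = file),
    class = "cctc_parameters")
  validate_cctc_parameters(out)
  out
}

#' Validate a CCTC parameter set
#'
#' Checks the structural invariants of the model: positive time constants,
#' positive maximum rates and slopes, and Dale-consistent connection signs
#' (weights out of CTX, VIM, DCN and STN must be non-negative; weights out of
#' NRT, GPe and GPi non-positive).
#'
#' @param params A `cctc_parameters` object.
#' @return `params`, invisibly; aborts with class
#'   `cctcsim_parameter_error` on violation.
#' @export
validate_cctc_parameters <- function(params) {
  tab <- params$populations
  if (any(!is.finite(tab$tau)) || any(tab$tau <= 0)) {
    abort("all population time constants must be positive and finite",
          class = "cctcsim_parameter_error")
  }
  if (any(tab$max_rate <= 0) || any(tab$slope <= 0)) {
    abort("sigmoid maximum rates and slopes must be positive",
          class = "cctcsim_parameter_error")
  }
  W <- params$W
  for (src in .excitatory) {
    if (any(W[src, ] < 0)) {
      abort(sprintf("weights out of excitatory population %s must be >= 0", src),
            class = "cctcsim_parameter_error")
    }
  }
  for (src in .inhibitory) {
    if (any(W[src, ] > 0)) {
      abort(sprintf("weights out of inhibitory population %s must be <= 0", src),
            class = "cctcsim_parameter_error")
    }
  }
  invisible(params)
}

#' @export
print.cctc_parameters <- function(x, ...) {
  cat("<cctc_parameters> 7-population CCTC loop rate model\n")
  cat("  file:", x$file, "\n")
  cat("  DCN baseline reference:", x$reference_rates$dcn_baseline, "spikes/s\n")
  cat("  connections:", sum(x$W != 0), "signed edges\n")
  print(x$populations)
  invisible(x)
}

#' Write a CCTC parameter set to YAML
#'
#' @param params A `cctc_parameters` object.
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_cctc_parameters <- function(params, file) {
  validate_cctc_parameters(params)
  tab <- params$populations
  pops <- as.list(tab$population)
  plist <- stats::setNames(lapply(seq_len(nrow(tab)), function(i) {
    list(tau = tab$tau[i], max_rate = tab$max_rate[i], slope = tab$slope[i],
         threshold = tab$threshold[i], background = tab$background[i])
  }), tab$population)
  idx <- which(params$W != 0, arr.ind = TRUE)
  conns <- lapply(seq_len(nrow(idx)), function(k) {
    list(from = rownames(params$W)[idx[k, 1]],
         to = colnames(params$W)[idx[k, 2]],
         weight = unname(params$W[idx[k, 1], idx[k, 2]]))
  })
  yaml::write_yaml(list(version = params$version, populations = plist,
                        reference_rates = params$reference_rates,
                        connections = conns,
                        stimulation = params$stimulation), file)
  invisible(file)
}
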