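#' Convert a half-life to an exponential time constant
#'
#' All decaying variables in the model are parameterised by half-lives;
#' internally each is converted to the time constant of the equivalent
#' exponential decay, \code{tau = lambda / ln 2}, so that a variable halves
#' every \code{lambda} time units.
#'
#' @param lambda Half-life, in any time unit. Must be positive.
#' @return Time constant in the same unit.
#' @examples
#' half_life_to_tau(log(2))  # 1
#' half_life_to_tau(2000)    # ~2885.39 ms
#' @export
half_life_to_tau <- function(lambda) {
  if (any(!is.finite(lambda)) || any(lambda <= 0))
    stop("half-life must be positive and finite")
  lambda / log(2)
}

#' Spiking model parameters
#'
#' Default values describe a representative phasically firing vasopressin
#' neuron under Poisson synaptic bombardment. Rates are in Hz, amplitudes in
#' mV, half-lives in ms, calcium quantities in nM; dynorphin is in arbitrary
#' units treated as nM-equivalent where it enters the leak term. Setting
#' \code{g_L = 0} removes the calcium-suppressed potassium leak and yields
#' an otherwise identical non-phasic (continuously firing) neuron.
#'
#' @param I_re Excitatory synaptic input rate (Hz).
#' @param I_ratio Inhibitory/excitatory input rate ratio.
#' @param e_h,i_h EPSP and IPSP amplitudes (mV); \code{i_h} is negative.
#' @param lambda_syn PSP half-life (ms).
#' @param k_HAP,lambda_HAP Hyperpolarising afterpotential increment per
#'   spike (mV) and half-life (ms).
#' @param k_DAP,lambda_DAP Fast depolarising afterpotential increment per
#'   spike (mV) and half-life (ms).
#' @param k_AHP,lambda_AHP,C_AHP Afterhyperpolarisation activation factor
#'   (mV/nM), half-life (ms), and minimum calcium excess for activation (nM).
#' @param C_rest Resting intracellular calcium (nM).
#' @param k_C,lambda_C Calcium increment per spike (nM) and half-life (ms).
#' @param k_D,lambda_D Dynorphin increment per spike (a.u.) and half-life (ms).
#' @param k_L Calcium sensitivity of the leak suppression (nM).
#' @param g_L Maximum voltage carried by the potassium leak (mV); 0 gives
#'   the non-phasic variant.
#' @param V_rest Resting potential with the leak fully suppressed (mV); the
#'   quiescent cell sits at \code{V_rest - g_L}.
#' @param V_thresh Spike threshold potential (mV).
#' @return An object of class \code{spiking_params}.
#' @examples
#' p <- spiking_params()
#' p_nonphasic <- spiking_params(g_L = 0)
#' @export
spiking_params <- function(I_re = 600, I_ratio = 1, e_h = 2, i_h = -2,
                           lambda_syn = 7.5,
                           k_HAP = 60, lambda_HAP = 9,
                           k_DAP = 0.5, lambda_DAP = 150,
                           k_AHP = 0.00012, lambda_AHP = 10000, C_AHP = 200,
                           C_rest = 113, k_C = 11, lambda_C = 2500,
                           k_D = 2.693, lambda_D = 7500,
                           k_L = 36, g_L = 8.5,
                           V_rest = -56, V_thresh = -50) {
  p <- list(I_re = I_re, I_ratio = I_ratio, e_h = e_h, i_h = i_h,
            lambda_syn = lambda_syn, k_HAP = k_HAP, lambda_HAP = lambda_HAP,
            k_DAP = k_DAP, lambda_DAP = lambda_DAP, k_AHP = k_AHP,
            lambda_AHP = lambda_AHP, C_AHP = C_AHP, C_rest = C_rest,
            k_C = k_C, lambda_C = lambda_C, k_D = k_D, lambda_D = lambda_D,
            k_L = k_L, g_L = g_L, V_rest = V_rest, V_thresh = V_thresh)
  validate_spiking_params(p)
  structure(p, class = "spiking_params")
}

validate_spiking_params <- function(p) {
  errs <- character()
  for (nm in c("lambda_syn", "lambda_HAP", "lambda_DAP", "lambda_AHP",
               "lambda_C", "lambda_D"))
    if (!is.finite(p[[nm]]) || p[[nm]] <= 0)
      errs <- c(errs, sprintf("%s: half-life must be positive", nm))
  if (p$I_re < 0) errs <- c(errs, "I_re: rate must be non-negative")
  if (p$I_ratio < 0) errs <- c(errs, "I_ratio: must be non-negative")
  if (p$k_HAP <= 0) errs <- c(errs, "k_HAP: must be positive")
  if (p$g_L < 0) errs <- c(errs, "g_L: must be non-negative")
  if (p$V_thresh <= p$V_rest)
    errs <- c(errs, "V_thresh: must exceed V_rest")
  if (length(errs)) stop(paste(errs, collapse = "; "))
  invisible(p)
}

#' Secretion model parameters
#'
#' Default values for the single-compartment terminal model of one
#' vasopressin cell: spike broadening \code{b}, cytosolic and submembrane
#' calcium \code{c} and \code{e} with their inverted-Hill inhibition of
#' calcium entry, the releasable pool \code{p} and reserve store \code{r}
#' (both in pg), and the plasma compartment \code{v}.
#'
#' @param k_b,lambda_b,b_base Broadening increment per spike, half-life
#'   (ms) and basal broadening.
#' @param k_c,lambda_c Maximum cytosolic calcium increment per spike and
#'   half-life (ms).
#' @param k_e,lambda_e Maximum submembrane calcium increment per spike and
#'   half-life (ms).
#' @param c_theta,c_n Threshold and gradient of the inverted Hill
#'   inhibition of calcium entry by \code{c} (fatigue).
#' @param e_theta,e_n Threshold and gradient of the inhibition by \code{e}
#'   (fast negative feedback).
#' @param beta Pool refill rate at a full reserve store (pg/s); the
#'   instantaneous rate is \code{beta * r / r_max}.
#' @param r_max Reserve store capacity (pg).
#' @param p_max Releasable pool capacity (pg).
#' @param alpha Secretion scaling factor (pg per unit of \code{e^3 * p}).
#' @param lambda_v Plasma vasopressin half-life (s).
#' @param fatigue_enabled If \code{FALSE} the cytosolic inhibition is
#'   clamped to 1 (\code{c_inhib = 1}), removing fatigue.
#' @return An object of class \code{secretion_params}.
#' @examples
#' q <- secretion_params()
#' q_fast_depletion <- secretion_params(r_max = 1e5)
#' @export
secretion_params <- function(k_b = 0.05, lambda_b = 2000, b_base = 0.5,
                             k_c = 0.0003, lambda_c = 20000,
                             k_e = 1.5, lambda_e = 100,
                             c_theta = 0.07, c_n = 5,
                             e_theta = 2.8, e_n = 5,
                             beta = 50, r_max = 1e6, p_max = 5000,
                             alpha = 5e-4, lambda_v = 120,
                             fatigue_enabled = TRUE) {
  q <- list(k_b = k_b, lambda_b = lambda_b, b_base = b_base,
            k_c = k_c, lambda_c = lambda_c, k_e = k_e, lambda_e = lambda_e,
            c_theta = c_theta, c_n = c_n, e_theta = e_theta, e_n = e_n,
            beta = beta, r_max = r_max, p_max = p_max, alpha = alpha,
            lambda_v = lambda_v, fatigue_enabled = isTRUE(fatigue_enabled))
  validate_secretion_params(q)
  structure(q, class = "secretion_params")
}

validate_secretion_params <- function(q) {
  errs <- character()
  for (nm in c("lambda_b", "lambda_c", "lambda_e", "lambda_v"))
    if (!is.finite(q[[nm]]) || q[[nm]] <= 0)
      errs <- c(errs, sprintf("%s: half-life must be positive", nm))
  if (q$c_n < 1 || q$e_n < 1)
    errs <- c(errs, "Hill coefficients must be >= 1")
  if (q$c_theta <= 0 || q$e_theta <= 0)
    errs <- c(errs, "Hill thresholds must be positive")
  if (q$p_max > q$r_max)
    errs <- c(errs, "p_max: must not exceed r_max")
  if (q$alpha <= 0) errs <- c(errs, "alpha: must be positive")
  if (q$beta < 0) errs <- c(errs, "beta: must be non-negative")
  if (length(errs)) stop(paste(errs, collapse = "; "))
  invisible(q)
}

#' Enable or disable secretion fatigue
#'
#' Returns a copy of the parameters with the cytosolic-calcium inhibition of
#' calcium entry toggled. With fatigue off, \code{c_inhib} is fixed at 1;
#' the fast submembrane inhibition (\code{e_inhib}) is unaffected.
#'
#' @param params A \code{secretion_params} object.
#' @param enabled Logical.
#' @return Modified \code{secretion_params}.
#' @export
set_fatigue <- function(params, enabled) {
  stopifnot(inherits(params, "secretion_params"))
  params$fatigue_enabled <- isTRUE(enabled)
  params
}

#' @export
print.spiking_params <- function(x, ...) {
  cat("Spiking model parameters",
      if (x$g_L == 0) "(non-phasic variant)" else "(phasic)", "\n")
  cat(sprintf("  input: I_re = %g Hz, I_ratio = %g, PSP %g/%g mV (t1/2 %g ms)\n",
              x$I_re, x$I_ratio, x$e_h, x$i_h, x$lambda_syn))
  cat(sprintf("  V_rest = %g mV, V_thresh = %g mV, g_L = %g mV\n",
              x$V_rest, x$V_thresh, x$g_L))
  invisible(x)
}

#' @export
print.secretion_params <- function(x, ...) {
  cat("Secretion model parameters\n")
  cat(sprintf("  pools: p_max = %g pg, r_max = %g pg, beta = %g pg/s\n",
              x$p_max, x$r_max, x$beta))
  cat(sprintf("  fatigue %s, alpha = %g pg/unit, lambda_v = %g s\n",
              if (x$fatigue_enabled) "enabled" else "disabled (c_inhib = 1)",
              x$alpha, x$lambda_v))
  invisible(x)
}

# fixed parameter orderings shared with the C++ steppers
.spiking_par_vec <- function(p) {
  as.numeric(p[c("I_re", "I_ratio", "e_h", "i_h", "lambda_syn", "k_HAP",
                 "lambda_HAP", "k_DAP", "lambda_DAP", "k_AHP", "lambda_AHP",
                 "C_AHP", "C_rest", "k_C", "lambda_C", "k_D", "lambda_D",
                 "k_L", "g_L", "V_rest", "V_thresh")])
}

.secretion_par_vec <- function(q) {
  as.numeric(q[c("k_b", "lambda_b", "b_base", "k_c", "lambda_c", "k_e",
                 "lambda_e", "c_theta", "c_n", "e_theta", "e_n", "beta",
                 "r_max", "p_max", "alpha", "lambda_v")])
}
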