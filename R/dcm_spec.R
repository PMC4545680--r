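#' Region and input labels of the three-region network
#'
#' Regions: anterior insular cortex (AIC), extrastriate body area (EBA),
#' lateral prefrontal cortex (LPFC). Inputs: u1 "all images" (driving input,
#' delivered to EBA in every model), u2 "painful images" (modulatory input).
#'
#' @return List with `regions` and `inputs`.
#' @export
dcm_regions <- function() {
  list(regions = c("AIC", "EBA", "LPFC"),
       inputs = c("all_images", "painful_images"))
}

#' Construct one DCM specification
#'
#' Connectivity masks for a bilinear three-region DCM. The fixed (A) mask
#' always allows all six extrinsic connections plus the three
#' self-connections; the driving input always targets EBA. The modulatory
#' mask is free within the catalogued patterns: painful images may modulate
#' the three self-connections and/or extrinsic connections between AIC/EBA
#' and LPFC (never the direct AIC-EBA links).
#'
#' @param name Model name.
#' @param b_self Logical: painful images modulate the three self-connections.
#' @param b_extrinsic One of "none", "forward" (AIC,EBA -> LPFC), "backward"
#'   (LPFC -> AIC,EBA) or "reciprocal".
#' @return Object of class `dcm_spec` with `a_mask`, `b_mask` (for the
#'   painful-images input), `c_mask`, `regions`, `inputs`, `name`.
#' @export
dcm_spec <- function(name, b_self,
                     b_extrinsic = c("none", "forward", "backward",
                                     "reciprocal")) {
  b_extrinsic <- match.arg(b_extrinsic)
  rg <- dcm_regions()
  n <- length(rg$regions)
  a_mask <- matrix(TRUE, n, n, dimnames = list(rg$regions, rg$regions))
  b_mask <- matrix(FALSE, n, n, dimnames = list(rg$regions, rg$regions))
  if (b_self) diag(b_mask) <- TRUE
  # entry [i, j] is the connection from j to i
  if (b_extrinsic %in% c("forward", "reciprocal")) {
    b_mask["LPFC", "AIC"] <- TRUE
    b_mask["LPFC", "EBA"] <- TRUE
  }
  if (b_extrinsic %in% c("backward", "reciprocal")) {
    b_mask["AIC", "LPFC"] <- TRUE
    b_mask["EBA", "LPFC"] <- TRUE
  }
  c_mask <- matrix(FALSE, n, 2, dimnames = list(rg$regions, rg$inputs))
  c_mask["EBA", "all_images"] <- TRUE
  structure(list(name = name, regions = rg$regions, inputs = rg$inputs,
                 a_mask = a_mask, b_mask = b_mask, c_mask = c_mask,
                 b_self = b_self, b_extrinsic = b_extrinsic),
            class = "dcm_spec")
}

#' The eight-model space
#'
#' Models 1-4 leave the self-connections unmodulated; models 5-8 let painful
#' images modulate all three self-connections. Within each quartet the
#' extrinsic modulation pattern is: none, forward (AIC and EBA to LPFC),
#' backward (LPFC to AIC and EBA), reciprocal.
#'
#' @return List of 8 `dcm_spec` objects named `model1` ... `model8`.
#' @export
dcm_model_space <- function() {
  pat <- c("none", "forward", "backward", "reciprocal")
  specs <- c(
    lapply(1:4, function(i) dcm_spec(paste0("model", i), FALSE, pat[i])),
    lapply(5:8, function(i) dcm_spec(paste0("model", i), TRUE, pat[i - 4]))
  )
  names(specs) <- paste0("model", 1:8)
  specs
}

#' The intrinsic-modulation family partition
#'
#' @return Named list: `no_intrinsic` (models 1-4), `intrinsic` (models 5-8).
#' @export
dcm_families <- function() {
  list(no_intrinsic = 1:4, intrinsic = 5:8)
}

#' Construct a set of DCM parameters
#'
#' `A`, `B` and `C` are stored as matrices in the masks' shape. Off-diagonal
#' entries of `A` and `B` are rate constants in Hz. The leading diagonals are
#' log-scale parameters: the effective self-connection under modulatory input
#' `u` is `-0.5 * exp(A_ii + u * B_ii)` Hz, so a negative diagonal `B` entry
#' attenuates self-inhibition (disinhibition) during painful images.
#'
#' @param A n x n fixed connectivity (diagonal on the log scale).
#' @param B n x n modulation by painful images (diagonal on the log scale);
#'   entries outside a model's mask should be 0.
#' @param C n x 2 driving gains (only `EBA, all_images` is nonzero by
#'   convention).
#' @param check_stability Error if the fixed-connectivity Jacobian at zero
#'   input has an eigenvalue with non-negative real part.
#' @return Object of class `dcm_params`.
#' @export
dcm_params <- function(A, B, C, check_stability = TRUE) {
  rg <- dcm_regions()
  n <- length(rg$regions)
  stopifnot(is.matrix(A), all(dim(A) == n),
            is.matrix(B), all(dim(B) == n),
            is.matrix(C), all(dim(C) == c(n, 2)))
  dimnames(A) <- dimnames(B) <- list(rg$regions, rg$regions)
  dimnames(C) <- list(rg$regions, rg$inputs)
  p <- structure(list(A = A, B = B, C = C), class = "dcm_params")
  if (check_stability && !dcm_stable(p)) {
    ev <- eigen(dcm_jacobian(p, 0), only.values = TRUE)$values
    stop("unstable fixed connectivity; eigenvalue real parts: ",
         paste(signif(Re(ev), 3), collapse = ", "))
  }
  p
}

#' Effective neural Jacobian at a given modulatory input level
#'
#' @param params A `dcm_params`.
#' @param u2 Level of the painful-images input (0 = baseline).
#' @return n x n matrix in Hz.
#' @export
dcm_jacobian <- function(params, u2 = 0) {
  J <- params$A + u2 * params$B
  diag(J) <- -0.5 * exp(diag(params$A) + u2 * diag(params$B))
  J
}

#' Is the neural system stable at rest?
#'
#' @param params A `dcm_params`.
#' @return `TRUE` if all eigenvalues of the zero-input Jacobian have negative
#'   real parts.
#' @export
dcm_stable <- function(params) {
  ev <- eigen(dcm_jacobian(params, 0), only.values = TRUE)$values
  all(Re(ev) < 0)
}

#' Ground-truth parameters used by the synthetic-data generator
#'
#' Plausible coupling strengths for the full model (model 8): moderate
#' positive extrinsic connections (0.1-0.25 Hz), unit-scale self-decay
#' (-0.5 Hz), pain-related disinhibition of all three regions (negative
#' log-scale diagonal B) and positive modulation of the
#' extrinsic AIC/EBA-LPFC loops. Entries outside the requested model's mask
#' are zeroed.
#'
#' @param model Model index 1-8 (default 8, the full model).
#' @param b_aic_self Log-scale pain modulation of the AIC self-connection
#'   (default -0.4; more negative = stronger disinhibition).
#' @return A `dcm_params`.
#' @export
dcm_ground_truth <- function(model = 8, b_aic_self = -0.4) {
  rg <- dcm_regions()$regions
  A <- matrix(c(0.00, 0.15, 0.10,
                0.05, 0.00, 0.10,
                0.10, 0.15, 0.00),
              3, 3, byrow = TRUE, dimnames = list(rg, rg))
  B <- matrix(0, 3, 3, dimnames = list(rg, rg))
  diag(B) <- c(b_aic_self, -0.4, -0.4)
  B["LPFC", "AIC"] <- 0.10
  B["LPFC", "EBA"] <- 0.10
  B["AIC", "LPFC"] <- 0.10
  B["EBA", "LPFC"] <- 0.10
  C <- matrix(0, 3, 2, dimnames = list(rg, dcm_regions()$inputs))
  C["EBA", "all_images"] <- 0.25
  spec <- dcm_model_space()[[model]]
  B[!spec$b_mask] <- 0
  dcm_params(A, B, C)
}

#' Hemodynamic forward-model parameters
#'
#' Balloon-type observation model shared by all regions: vasodilatory signal
#' decay rate, inflow autoregulation rate, mean transit time, vessel
#' stiffness exponent, resting oxygen extraction fraction, and resting
#' venous blood volume fraction. Defaults are the standard literature values;
#' they are fixed (not estimated) during inversion.
#'
#' @param signal_decay 1/s (default 0.65).
#' @param autoregulation 1/s (default 0.41).
#' @param transit_time s (default 0.98).
#' @param stiffness Unitless Grubb exponent (default 0.32).
#' @param oxygen_extraction Resting fraction (default 0.34).
#' @param volume_fraction Resting venous volume fraction (default 0.04).
#' @return Named numeric vector of class `hemo_params`.
#' @export
hemodynamic_params <- function(signal_decay = 0.65, autoregulation = 0.41,
                               transit_time = 0.98, stiffness = 0.32,
                               oxygen_extraction = 0.34,
                               volume_fraction = 0.04) {
  p <- c(signal_decay = signal_decay, autoregulation = autoregulation,
         transit_time = transit_time, stiffness = stiffness,
         oxygen_extraction = oxygen_extraction,
         volume_fraction = volume_fraction)
  if (any(p <= 0)) stop("hemodynamic parameters must be positive")
  structure(p, class = "hemo_params")
}
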