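# Reference kinetic parameters and abundances of the simplified carousel model.

#' Kinetic parameters of the simplified carousel model
#'
#' Construct the 12 rate/affinity constants of the simplified carousel model of
#' GPCR-catalysed G-protein activation. Defaults are the reference values
#' measured (or estimated) for the yeast pheromone response system. The
#' occupied-receptor hydrolysis rate `kH_LRGt` defaults to `kH_RGt`,
#' encoding receptor-localized RGS (GAP) activity:
#' `kH_LRGt ~ kH_RGt >> kH_Gt`.
#'
#' On-rates are derived, not free: `kon_LR = koff_LR / Kd_LR`,
#' `kon_RG = koff_RG / Kd_RG`, and `koff_GdGbg = kA_Gd * Kd_GdGbg`, so that
#' micro-reversibility of the binding/coupling sub-network holds at any
#' parameter point.
#'
#' @param Kd_LR ligand-receptor dissociation constant, nM.
#' @param koff_LR ligand-receptor off-rate, 1/s.
#' @param Kd_RG receptor-Galpha dissociation constant, nM.
#' @param koff_RG receptor-Galpha off-rate, 1/s. Sets the coupling regime:
#'   small values give precoupling (ternary-complex), large values
#'   collision coupling.
#' @param Kd_GdGbg GalphaGDP-Gbetagamma dissociation constant, nM.
#' @param kA_Gd GalphaGDP + Gbetagamma association rate, 1/(nM s).
#' @param kE_G GDP/GTP exchange (and trimer dissociation) rate of the free
#'   heterotrimer, 1/s.
#' @param kE_RG exchange rate of Galpha coupled to an unoccupied receptor, 1/s.
#' @param kE_LRG exchange rate of Galpha coupled to a ligand-occupied receptor
#'   (the receptor's GEF activity), 1/s.
#' @param kH_Gt GTP hydrolysis rate of uncoupled GalphaGTP, 1/s.
#' @param kH_RGt hydrolysis rate of GalphaGTP coupled to an unoccupied
#'   receptor (receptor-localized RGS GAP activity), 1/s.
#' @param kH_LRGt hydrolysis rate of GalphaGTP coupled to an occupied
#'   receptor; default `kH_RGt`.
#' @return A named list of class `carousel_params` with the 12 primary
#'   parameters plus the derived `kon_LR`, `kon_RG`, `koff_GdGbg`.
#' @examples
#' p <- carousel_params()
#' p$kH_RGt / p$kH_Gt   # GAP fold-acceleration at the receptor, > 20
#' @export
carousel_params <- function(Kd_LR = 5.6,
                            koff_LR = 0.001,
                            Kd_RG = 33,
                            koff_RG = 0.1,
                            Kd_GdGbg = 0.01,
                            kA_Gd = 3.2,
                            kE_G = 0.00062,
                            kE_RG = 0.00062,
                            kE_LRG = 1.5,
                            kH_Gt = 0.002,
                            kH_RGt = 0.11,
                            kH_LRGt = kH_RGt) {
  p <- list(
    Kd_LR = Kd_LR, koff_LR = koff_LR,
    Kd_RG = Kd_RG, koff_RG = koff_RG,
    Kd_GdGbg = Kd_GdGbg, kA_Gd = kA_Gd,
    kE_G = kE_G, kE_RG = kE_RG, kE_LRG = kE_LRG,
    kH_Gt = kH_Gt, kH_RGt = kH_RGt, kH_LRGt = kH_LRGt
  )
  validate_params(p)
  p$kon_LR <- p$koff_LR / p$Kd_LR
  p$kon_RG <- p$koff_RG / p$Kd_RG
  p$koff_GdGbg <- p$kA_Gd * p$Kd_GdGbg
  class(p) <- "carousel_params"
  p
}

#' Names of the 12 primary (sampleable) kinetic parameters
#' @return Character vector of parameter names.
#' @export
kinetic_parameter_names <- function() {
  c("Kd_LR", "koff_LR", "Kd_RG", "koff_RG", "Kd_GdGbg", "kA_Gd",
    "kE_G", "kE_RG", "kE_LRG", "kH_Gt", "kH_RGt", "kH_LRGt")
}

validate_params <- function(p) {
  kds <- c("Kd_LR", "Kd_RG", "Kd_GdGbg")
  for (nm in kinetic_parameter_names()) {
    v <- p[[nm]]
    strict <- nm %in% kds
    if (is.null(v) || !is.numeric(v) || length(v) != 1L || !is.finite(v) ||
        (strict && v <= 0) || (!strict && v < 0)) {
      stop("parameter '", nm, "' must be a single finite ",
           if (strict) "positive" else "non-negative", " number",
           call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' Coerce a named list/vector to carousel_params
#'
#' Unknown names are rejected; missing names fall back to the reference values.
#'
#' @param x named list or numeric vector of primary kinetic parameters.
#' @return A `carousel_params` object.
#' @export
as_carousel_params <- function(x) {
  if (inherits(x, "carousel_params")) return(x)
  x <- as.list(x)
  known <- kinetic_parameter_names()
  bad <- setdiff(names(x), known)
  if (length(bad)) {
    stop("unknown kinetic parameter(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  # kH_LRGt tracks kH_RGt unless given explicitly
  if (is.null(x$kH_LRGt) && !is.null(x$kH_RGt)) x$kH_LRGt <- x$kH_RGt
  do.call(carousel_params, x)
}

#' @export
print.carousel_params <- function(x, ...) {
  cat("Carousel model kinetic parameters (nM, s):\n")
  v <- unlist(x[kinetic_parameter_names()])
  print(signif(v, 4))
  cat("derived: kon_LR =", signif(x$kon_LR, 4),
      " kon_RG =", signif(x$kon_RG, 4),
      " koff_GdGbg =", signif(x$koff_GdGbg, 4), "\n")
  invisible(x)
}

#' Total receptor and G-protein abundances
#'
#' Defaults are the reference totals for the yeast pheromone system:
#' 1,400 nM receptor and 860 nM G protein (Galpha total = Gbetagamma total).
#' `V_cyt` (cytoplasmic volume, fl) is carried for conversion between
#' concentrations and molecule counts.
#'
#' @param R_tot total receptor, nM.
#' @param G_tot total G protein, nM.
#' @param V_cyt cell volume used for molecule-count conversion, fl.
#' @return A named list of class `carousel_abundances`.
#' @export
carousel_abundances <- function(R_tot = 1400, G_tot = 860, V_cyt = 36.4) {
  if (!is.numeric(R_tot) || length(R_tot) != 1L || !is.finite(R_tot) ||
      R_tot < 0) stop("R_tot must be a single finite non-negative number")
  if (!is.numeric(G_tot) || length(G_tot) != 1L || !is.finite(G_tot) ||
      G_tot < 0) stop("G_tot must be a single finite non-negative number")
  if (!is.numeric(V_cyt) || length(V_cyt) != 1L || !is.finite(V_cyt) ||
      V_cyt <= 0) stop("V_cyt must be a single positive number")
  structure(list(R_tot = R_tot, G_tot = G_tot, V_cyt = V_cyt),
            class = "carousel_abundances")
}

#' Extended-model RGS parameters
#'
#' Parameters added by the extended carousel variant, in which RGS binding to
#' the receptor is an explicit reversible reaction. Receptor-coupled GalphaGTP
#' hydrolyzes at the Table-of-reference rates only when the receptor carries
#' an RGS; without RGS it hydrolyzes at the basal rate `kH_noRGS_RGt`.
#'
#' @param RGS_tot total RGS, molecules per cell.
#' @param Kd_R_RGS receptor-RGS dissociation constant, nM.
#' @param kH_noRGS_RGt hydrolysis rate of receptor-coupled GalphaGTP on an
#'   RGS-free receptor, 1/s (basal, equal to the uncoupled rate).
#' @param kon_R_RGS RGS-receptor association rate, 1/(nM s). The off-rate is
#'   derived as `kon_R_RGS * Kd_R_RGS`.
#' @param V_cyt cell volume used to convert `RGS_tot` to nM, fl.
#' @return A named list of class `rgs_params` including the derived
#'   `koff_R_RGS` and `RGS_tot_nM`.
#' @export
rgs_params <- function(RGS_tot = 6000, Kd_R_RGS = 383,
                       kH_noRGS_RGt = 0.002, kon_R_RGS = 0.01,
                       V_cyt = 36.4) {
  vals <- c(RGS_tot = RGS_tot, Kd_R_RGS = Kd_R_RGS,
            kH_noRGS_RGt = kH_noRGS_RGt, kon_R_RGS = kon_R_RGS,
            V_cyt = V_cyt)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("all RGS parameters must be finite and positive")
  }
  structure(list(RGS_tot = RGS_tot, Kd_R_RGS = Kd_R_RGS,
                 kH_noRGS_RGt = kH_noRGS_RGt, kon_R_RGS = kon_R_RGS,
                 koff_R_RGS = kon_R_RGS * Kd_R_RGS,
                 RGS_tot_nM = molecules_to_nM(RGS_tot, V_cyt),
                 V_cyt = V_cyt),
            class = "rgs_params")
}

AVOGADRO <- 6.02214076e23

#' Convert molecule counts to nM (and back)
#'
#' `concentration [nM] = count / (N_A * V [L]) * 1e9` with `V` in femtoliters.
#'
#' @param count molecules per cell (non-negative).
#' @param V cell volume, fl.
#' @return Concentration in nM.
#' @export
molecules_to_nM <- function(count, V = 36.4) {
  if (any(count < 0)) stop("count must be non-negative")
  if (any(V <= 0)) stop("volume must be positive")
  count / (AVOGADRO * V * 1e-15) / 1e-9
}

#' @rdname molecules_to_nM
#' @param conc concentration, nM.
#' @return `nM_to_molecules`: molecules per cell.
#' @export
nM_to_molecules <- function(conc, V = 36.4) {
  if (any(conc < 0)) stop("concentration must be non-negative")
  if (any(V <= 0)) stop("volume must be positive")
  conc * 1e-9 * AVOGADRO * V * 1e-15
}
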