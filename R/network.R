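# Carousel reaction network: species, mass-action reactions, conservation laws.
#
# The network composes the ternary complex model (ligand binding, receptor-G
# coupling) with the three-state G-protein cycle (exchange, hydrolysis,
# reassociation). Ligand L is a clamped external concentration, not a state
# variable. All binding/coupling/reassociation reactions are reversible; GTP
# loading (exchange) and hydrolysis are irreversible, being driven by GTP
# turnover.

SIMPLIFIED_SPECIES <- c("R", "LR", "RG", "LRG", "RGt", "LRGt",
                        "RGd", "LRGd", "G", "Gt", "Gd", "Gbg")

#' Build a carousel reaction network
#'
#' Constructs the mass-action network of one of three model variants:
#' \describe{
#'   \item{simplified}{12 species, 19 reactions. Eight receptor forms
#'     (free/ligand-occupied crossed with uncoupled or coupled to the trimer,
#'     GalphaGTP or GalphaGDP) and four free G-protein forms.}
#'   \item{extended}{RGS-receptor binding made explicit: the eight receptor
#'     forms are duplicated into RGS-free and RGS-bound versions (eight
#'     RGS association reactions), and only RGS-bound receptors confer the
#'     accelerated GAP hydrolysis rates.}
#'   \item{two_pool}{Two co-expressed receptor pools sharing one G-protein
#'     pool; pool 2 may be unable to bind ligand (a dominant-negative
#'     receptor), in which case it retains full coupling and GAP activity but
#'     has no ligand-binding reactions.}
#' }
#'
#' Symmetry assumptions (defaults of the simplified model): one kon/koff pair
#' for all ligand-binding reactions, one for all coupling reactions, one
#' kA/koff pair for all reassociation reactions. These identifications reduce
#' the model to 13 parameters and make every closed binding/coupling loop
#' thermodynamically consistent.
#'
#' @param variant one of "simplified", "extended", "two_pool".
#' @param params a [carousel_params()] object (or coercible named list).
#' @param rgs an [rgs_params()] object; required for `variant = "extended"`.
#' @param pool2 a list describing the second receptor pool for
#'   `variant = "two_pool"`; supported field `binds_ligand` (logical,
#'   default `FALSE`).
#' @return A `carousel_network` object: species names, stoichiometry matrix
#'   `S` (species x reactions), forward/reverse rate constants and reactant
#'   index lists, the ligand flag per reaction, and the conservation matrix
#'   `cons` whose rows annihilate `S`.
#' @export
build_network <- function(variant = c("simplified", "extended", "two_pool"),
                          params = carousel_params(), rgs = NULL,
                          pool2 = NULL) {
  variant <- match.arg(variant)
  params <- as_carousel_params(params)
  switch(variant,
    simplified = build_simplified(params),
    extended = {
      if (is.null(rgs)) stop("extended variant requires 'rgs' parameters")
      if (!inherits(rgs, "rgs_params")) rgs <- do.call(rgs_params, rgs)
      build_extended(params, rgs)
    },
    two_pool = {
      if (is.null(pool2)) pool2 <- list(binds_ligand = FALSE)
      build_two_pool(params, isTRUE(pool2$binds_ligand))
    }
  )
}

# internal incremental network assembler
new_net_builder <- function(species) {
  env <- new.env(parent = emptyenv())
  env$species <- species
  env$fwd <- list(); env$rev <- list()
  env$kf <- numeric(); env$kr <- numeric(); env$lig <- logical()
  env$name <- character()
  env
}

add_rxn <- function(b, from, to, kf, kr = 0, lig = FALSE, name = "") {
  i <- match(from, b$species); j <- match(to, b$species)
  if (anyNA(i) || anyNA(j)) stop("unknown species in reaction ", name)
  b$fwd[[length(b$fwd) + 1L]] <- i
  b$rev[[length(b$rev) + 1L]] <- j
  b$kf <- c(b$kf, kf); b$kr <- c(b$kr, kr); b$lig <- c(b$lig, lig)
  b$name <- c(b$name, name)
  invisible(b)
}

finish_network <- function(b, variant, params, cons, extra = list()) {
  ns <- length(b$species); nr <- length(b$kf)
  S <- matrix(0, ns, nr, dimnames = list(b$species, b$name))
  for (j in seq_len(nr)) {
    for (i in b$fwd[[j]]) S[i, j] <- S[i, j] - 1
    for (i in b$rev[[j]]) S[i, j] <- S[i, j] + 1
  }
  net <- c(list(variant = variant, species = b$species, params = params,
                S = S, kf = b$kf, kr = b$kr, fwd = b$fwd, rev = b$rev,
                lig = b$lig, reaction = b$name, cons = cons),
           extra)
  class(net) <- "carousel_network"
  net
}

build_simplified <- function(p) {
  b <- new_net_builder(SIMPLIFIED_SPECIES)
  # 4 reversible ligand-binding reactions (forward rate kon_LR * L)
  for (sp in c("R", "RG", "RGt", "RGd")) {
    add_rxn(b, sp, paste0("L", sp), p$kon_LR, p$koff_LR, lig = TRUE,
            name = paste0("L+", sp))
  }
  # 6 reversible coupling reactions {R,LR} x {G,Gt,Gd}
  for (r in c("R", "LR")) for (g in c("G", "Gt", "Gd")) {
    cpl <- if (g == "G") paste0(r, "G") else paste0(r, g)
    add_rxn(b, c(r, g), cpl, p$kon_RG, p$koff_RG, name = paste0(r, "+", g))
  }
  # 3 irreversible exchange reactions releasing Gbg
  add_rxn(b, "G", c("Gt", "Gbg"), p$kE_G, name = "exch_G")
  add_rxn(b, "RG", c("RGt", "Gbg"), p$kE_RG, name = "exch_RG")
  add_rxn(b, "LRG", c("LRGt", "Gbg"), p$kE_LRG, name = "exch_LRG")
  # 3 irreversible hydrolysis reactions
  add_rxn(b, "Gt", "Gd", p$kH_Gt, name = "hyd_Gt")
  add_rxn(b, "RGt", "RGd", p$kH_RGt, name = "hyd_RGt")
  add_rxn(b, "LRGt", "LRGd", p$kH_LRGt, name = "hyd_LRGt")
  # 3 reversible reassociation reactions
  add_rxn(b, c("Gd", "Gbg"), "G", p$kA_Gd, p$koff_GdGbg, name = "assoc_Gd")
  add_rxn(b, c("RGd", "Gbg"), "RG", p$kA_Gd, p$koff_GdGbg, name = "assoc_RGd")
  add_rxn(b, c("LRGd", "Gbg"), "LRG", p$kA_Gd, p$koff_GdGbg,
          name = "assoc_LRGd")

  cons <- rbind(
    R_tot   = as.numeric(b$species %in% c("R", "LR", "RG", "LRG", "RGt",
                                          "LRGt", "RGd", "LRGd")),
    Ga_tot  = as.numeric(b$species %in% c("RG", "LRG", "RGt", "LRGt", "RGd",
                                          "LRGd", "G", "Gt", "Gd")),
    Gbg_tot = as.numeric(b$species %in% c("Gbg", "G", "RG", "LRG"))
  )
  colnames(cons) <- b$species
  finish_network(b, "simplified", p, cons)
}

build_extended <- function(p, rgs) {
  base <- SIMPLIFIED_SPECIES[1:8]
  bound <- paste0(base, "_RGS")
  species <- c(base, bound, "G", "Gt", "Gd", "Gbg", "RGS")
  b <- new_net_builder(species)
  for (suf in c("", "_RGS")) {
    for (sp in c("R", "RG", "RGt", "RGd")) {
      add_rxn(b, paste0(sp, suf), paste0("L", sp, suf), p$kon_LR, p$koff_LR,
              lig = TRUE, name = paste0("L+", sp, suf))
    }
    for (r in c("R", "LR")) for (g in c("G", "Gt", "Gd")) {
      cpl <- paste0(r, if (g == "G") "G" else g, suf)
      add_rxn(b, c(paste0(r, suf), g), cpl, p$kon_RG, p$koff_RG,
              name = paste0(r, suf, "+", g))
    }
    add_rxn(b, paste0("RG", suf), c(paste0("RGt", suf), "Gbg"), p$kE_RG,
            name = paste0("exch_RG", suf))
    add_rxn(b, paste0("LRG", suf), c(paste0("LRGt", suf), "Gbg"), p$kE_LRG,
            name = paste0("exch_LRG", suf))
    # GAP acceleration only on RGS-bound receptor
    kH_R <- if (suf == "_RGS") p$kH_RGt else rgs$kH_noRGS_RGt
    kH_LR <- if (suf == "_RGS") p$kH_LRGt else rgs$kH_noRGS_RGt
    add_rxn(b, paste0("RGt", suf), paste0("RGd", suf), kH_R,
            name = paste0("hyd_RGt", suf))
    add_rxn(b, paste0("LRGt", suf), paste0("LRGd", suf), kH_LR,
            name = paste0("hyd_LRGt", suf))
    add_rxn(b, c(paste0("RGd", suf), "Gbg"), paste0("RG", suf), p$kA_Gd,
            p$koff_GdGbg, name = paste0("assoc_RGd", suf))
    add_rxn(b, c(paste0("LRGd", suf), "Gbg"), paste0("LRG", suf), p$kA_Gd,
            p$koff_GdGbg, name = paste0("assoc_LRGd", suf))
  }
  add_rxn(b, "G", c("Gt", "Gbg"), p$kE_G, name = "exch_G")
  add_rxn(b, "Gt", "Gd", p$kH_Gt, name = "hyd_Gt")
  add_rxn(b, c("Gd", "Gbg"), "G", p$kA_Gd, p$koff_GdGbg, name = "assoc_Gd")
  # eight RGS-receptor association reactions, one per receptor form
  for (sp in base) {
    add_rxn(b, c(sp, "RGS"), paste0(sp, "_RGS"), rgs$kon_R_RGS,
            rgs$koff_R_RGS, name = paste0("RGS+", sp))
  }

  has_ga <- function(s) grepl("G(t|d)?(_RGS)?$", s) & !(s %in% c("Gbg", "RGS"))
  cons <- rbind(
    R_tot   = as.numeric(species %in% c(base, bound)),
    Ga_tot  = as.numeric(species %in% c("G", "Gt", "Gd") |
                           (species %in% c(base, bound) & has_ga(species))),
    Gbg_tot = as.numeric(species %in% c("Gbg", "G", "RG", "LRG",
                                        "RG_RGS", "LRG_RGS")),
    RGS_tot = as.numeric(species == "RGS" | species %in% bound)
  )
  colnames(cons) <- species
  finish_network(b, "extended", p, cons, extra = list(rgs = rgs))
}

build_two_pool <- function(p, pool2_binds_ligand) {
  pool2 <- if (pool2_binds_ligand) {
    paste0(c("R2", "LR2", "R2G", "LR2G", "R2Gt", "LR2Gt", "R2Gd", "LR2Gd"))
  } else {
    c("R2", "R2G", "R2Gt", "R2Gd")
  }
  species <- c(SIMPLIFIED_SPECIES[1:8], pool2, "G", "Gt", "Gd", "Gbg")
  b <- new_net_builder(species)
  # pool 1: identical to the simplified network's receptor reactions
  for (sp in c("R", "RG", "RGt", "RGd")) {
    add_rxn(b, sp, paste0("L", sp), p$kon_LR, p$koff_LR, lig = TRUE,
            name = paste0("L+", sp))
  }
  for (r in c("R", "LR")) for (g in c("G", "Gt", "Gd")) {
    cpl <- if (g == "G") paste0(r, "G") else paste0(r, g)
    add_rxn(b, c(r, g), cpl, p$kon_RG, p$koff_RG, name = paste0(r, "+", g))
  }
  add_rxn(b, "RG", c("RGt", "Gbg"), p$kE_RG, name = "exch_RG")
  add_rxn(b, "LRG", c("LRGt", "Gbg"), p$kE_LRG, name = "exch_LRG")
  add_rxn(b, "RGt", "RGd", p$kH_RGt, name = "hyd_RGt")
  add_rxn(b, "LRGt", "LRGd", p$kH_LRGt, name = "hyd_LRGt")
  add_rxn(b, c("RGd", "Gbg"), "RG", p$kA_Gd, p$koff_GdGbg, name = "assoc_RGd")
  add_rxn(b, c("LRGd", "Gbg"), "LRG", p$kA_Gd, p$koff_GdGbg,
          name = "assoc_LRGd")
  # pool 2: coupling and cycle; ligand binding only if the pool binds ligand
  if (pool2_binds_ligand) {
    for (sp in c("R2", "R2G", "R2Gt", "R2Gd")) {
      lsp <- sub("^R2", "LR2", sp)
      add_rxn(b, sp, lsp, p$kon_LR, p$koff_LR, lig = TRUE,
              name = paste0("L+", sp))
    }
  }
  r2 <- if (pool2_binds_ligand) c("R2", "LR2") else "R2"
  for (r in r2) for (g in c("G", "Gt", "Gd")) {
    cpl <- if (g == "G") paste0(r, "G") else paste0(r, g)
    add_rxn(b, c(r, g), cpl, p$kon_RG, p$koff_RG, name = paste0(r, "+", g))
  }
  add_rxn(b, "R2G", c("R2Gt", "Gbg"), p$kE_RG, name = "exch_R2G")
  add_rxn(b, "R2Gt", "R2Gd", p$kH_RGt, name = "hyd_R2Gt")
  add_rxn(b, c("R2Gd", "Gbg"), "R2G", p$kA_Gd, p$koff_GdGbg,
          name = "assoc_R2Gd")
  if (pool2_binds_ligand) {
    add_rxn(b, "LR2G", c("LR2Gt", "Gbg"), p$kE_LRG, name = "exch_LR2G")
    add_rxn(b, "LR2Gt", "LR2Gd", p$kH_LRGt, name = "hyd_LR2Gt")
    add_rxn(b, c("LR2Gd", "Gbg"), "LR2G", p$kA_Gd, p$koff_GdGbg,
            name = "assoc_LR2Gd")
  }
  # free-G cycle
  add_rxn(b, "G", c("Gt", "Gbg"), p$kE_G, name = "exch_G")
  add_rxn(b, "Gt", "Gd", p$kH_Gt, name = "hyd_Gt")
  add_rxn(b, c("Gd", "Gbg"), "G", p$kA_Gd, p$koff_GdGbg, name = "assoc_Gd")

  pool1 <- SIMPLIFIED_SPECIES[1:8]
  coupled <- c(pool1[3:8], setdiff(pool2, c("R2", "LR2")))
  trimer <- c("G", intersect(c("RG", "LRG", "R2G", "LR2G"), species))
  cons <- rbind(
    R_tot   = as.numeric(species %in% pool1),
    R2_tot  = as.numeric(species %in% pool2),
    Ga_tot  = as.numeric(species %in% c(coupled, "G", "Gt", "Gd")),
    Gbg_tot = as.numeric(species %in% c("Gbg", trimer))
  )
  colnames(cons) <- species
  finish_network(b, "two_pool", p, cons,
                 extra = list(pool2_binds_ligand = pool2_binds_ligand))
}

#' @export
print.carousel_network <- function(x, ...) {
  cat("Carousel network (", x$variant, "): ", length(x$species),
      " species, ", length(x$kf), " reactions, ",
      nrow(x$cons), " conservation laws\n", sep = "")
  invisible(x)
}

#' Mass-action reaction fluxes
#'
#' Net flux of every reaction at a given state and clamped ligand
#' concentration: `v = kf * [L]^lig * prod(reactants) - kr * prod(products)`.
#'
#' @param network a `carousel_network`.
#' @param state named non-negative concentration vector (nM), in the
#'   network's species order.
#' @param L clamped extracellular ligand concentration, nM.
#' @return Numeric vector of net reaction rates (nM/s).
#' @export
reaction_fluxes <- function(network, state, L) {
  check_state(network, state, L)
  v <- numeric(length(network$kf))
  for (j in seq_along(v)) {
    f <- network$kf[j] * prod(state[network$fwd[[j]]])
    if (network$lig[j]) f <- f * L
    r <- if (network$kr[j] > 0) network$kr[j] * prod(state[network$rev[[j]]])
         else 0
    v[j] <- f - r
  }
  v
}

check_state <- function(network, state, L) {
  if (length(state) != length(network$species)) {
    stop("state must have ", length(network$species), " species")
  }
  if (any(!is.finite(state)) || any(state < 0)) {
    stop("state concentrations must be finite and non-negative")
  }
  if (!is.finite(L) || L < 0) stop("L must be finite and non-negative")
  invisible(TRUE)
}

#' Time derivatives of the species concentrations
#'
#' Mass-action right-hand side `dx/dt = S v(x, L)`. The derivative of every
#' conserved total is structurally zero.
#'
#' @inheritParams reaction_fluxes
#' @return Named numeric vector of time derivatives (nM/s).
#' @export
rhs <- function(network, state, L) {
  v <- reaction_fluxes(network, state, L)
  d <- as.numeric(network$S %*% v)
  names(d) <- network$species
  d
}

# Analytic Jacobian of the mass-action rhs (species x species).
network_jacobian <- function(network, state, L) {
  ns <- length(network$species)
  J <- matrix(0, ns, ns)
  for (j in seq_along(network$kf)) {
    sj <- network$S[, j]
    fw <- network$fwd[[j]]
    kf <- network$kf[j] * if (network$lig[j]) L else 1
    for (m in seq_along(fw)) {
      dv <- kf * prod(state[fw[-m]])
      J[, fw[m]] <- J[, fw[m]] + sj * dv
    }
    if (network$kr[j] > 0) {
      rv <- network$rev[[j]]
      for (m in seq_along(rv)) {
        dv <- network$kr[j] * prod(state[rv[-m]])
        J[, rv[m]] <- J[, rv[m]] - sj * dv
      }
    }
  }
  dimnames(J) <- list(network$species, network$species)
  J
}

#' Conserved totals of a state
#'
#' The linear combinations of species that the network dynamics leave
#' invariant: total receptor, total Galpha, total Gbetagamma (plus RGS total
#' in the extended variant and the second receptor pool total in the two-pool
#' variant).
#'
#' @param state named concentration vector (nM).
#' @param network the `carousel_network` the state belongs to; defaults to the
#'   simplified variant when the state carries the 12 simplified species
#'   names.
#' @return Named numeric vector of conserved totals (nM).
#' @export
conserved_totals <- function(state, network = NULL) {
  if (is.null(network)) {
    if (!all(SIMPLIFIED_SPECIES %in% names(state))) {
      stop("state lacks simplified species names; pass the network")
    }
    state <- state[SIMPLIFIED_SPECIES]
    cons <- rbind(
      R_tot = as.numeric(SIMPLIFIED_SPECIES %in% SIMPLIFIED_SPECIES[1:8]),
      Ga_tot = as.numeric(SIMPLIFIED_SPECIES %in%
                            c(SIMPLIFIED_SPECIES[3:8], "G", "Gt", "Gd")),
      Gbg_tot = as.numeric(SIMPLIFIED_SPECIES %in% c("Gbg", "G", "RG", "LRG"))
    )
    return(drop(cons %*% state))
  }
  drop(network$cons %*% state[network$species])
}
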