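# Independent flux-by-flux right-hand-side oracle for the simplified model.
# Deliberately written reaction-by-reaction with explicit species names, not
# through the package's network machinery.
oracle_rhs <- function(p, x, L) {
  d <- stats::setNames(numeric(12), names(x))
  konLR <- p$koff_LR / p$Kd_LR
  konRG <- p$koff_RG / p$Kd_RG
  koffGG <- p$kA_Gd * p$Kd_GdGbg
  bind <- function(free, bound) {
    unname(konLR * L * x[free] - p$koff_LR * x[bound])
  }
  cpl <- function(r, g, c) {
    unname(konRG * x[r] * x[g] - p$koff_RG * x[c])
  }
  reas <- function(gd, c) {
    unname(p$kA_Gd * x[gd] * x["Gbg"] - koffGG * x[c])
  }

  v_bind <- c(R = bind("R", "LR"), RG = bind("RG", "LRG"),
              RGt = bind("RGt", "LRGt"), RGd = bind("RGd", "LRGd"))
  v_cpl <- c(RG = cpl("R", "G", "RG"), LRG = cpl("LR", "G", "LRG"),
             RGt = cpl("R", "Gt", "RGt"), LRGt = cpl("LR", "Gt", "LRGt"),
             RGd = cpl("R", "Gd", "RGd"), LRGd = cpl("LR", "Gd", "LRGd"))
  v_ex <- c(G = p$kE_G * unname(x["G"]), RG = p$kE_RG * unname(x["RG"]),
            LRG = p$kE_LRG * unname(x["LRG"]))
  v_hy <- c(Gt = p$kH_Gt * unname(x["Gt"]),
            RGt = p$kH_RGt * unname(x["RGt"]),
            LRGt = p$kH_LRGt * unname(x["LRGt"]))
  v_re <- c(G = reas("Gd", "G"), RG = reas("RGd", "RG"),
            LRG = reas("LRGd", "LRG"))

  d["R"] <- -v_bind["R"] - v_cpl["RG"] - v_cpl["RGt"] - v_cpl["RGd"]
  d["LR"] <- v_bind["R"] - v_cpl["LRG"] - v_cpl["LRGt"] - v_cpl["LRGd"]
  d["RG"] <- v_cpl["RG"] - v_bind["RG"] - v_ex["RG"] + v_re["RG"]
  d["LRG"] <- v_cpl["LRG"] + v_bind["RG"] - v_ex["LRG"] + v_re["LRG"]
  d["RGt"] <- v_cpl["RGt"] - v_bind["RGt"] + v_ex["RG"] - v_hy["RGt"]
  d["LRGt"] <- v_cpl["LRGt"] + v_bind["RGt"] + v_ex["LRG"] - v_hy["LRGt"]
  d["RGd"] <- v_cpl["RGd"] - v_bind["RGd"] + v_hy["RGt"] - v_re["RG"]
  d["LRGd"] <- v_cpl["LRGd"] + v_bind["RGd"] + v_hy["LRGt"] - v_re["LRG"]
  d["G"] <- -v_cpl["RG"] - v_cpl["LRG"] - v_ex["G"] + v_re["G"]
  d["Gt"] <- v_ex["G"] - v_hy["Gt"] - v_cpl["RGt"] - v_cpl["LRGt"]
  d["Gd"] <- v_hy["Gt"] - v_cpl["RGd"] - v_cpl["LRGd"] - v_re["G"]
  d["Gbg"] <- sum(v_ex) - v_re["G"] - v_re["RG"] - v_re["LRG"]
  d
}

simplified_species <- c("R", "LR", "RG", "LRG", "RGt", "LRGt",
                        "RGd", "LRGd", "G", "Gt", "Gd", "Gbg")

random_state <- function(seed = 1) {
  set.seed(seed)
  stats::setNames(stats::runif(12, 0, 100), simplified_species)
}

# a moderately perturbed parameter draw (log-uniform around the reference)
random_params <- function(seed, span = 4) {
  set.seed(seed)
  ref <- carousel_params()
  vals <- lapply(kinetic_parameter_names(), function(nm) {
    ref[[nm]] * 10^stats::runif(1, -span / 2, span / 2)
  })
  names(vals) <- kinetic_parameter_names()
  as_carousel_params(vals)
}
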