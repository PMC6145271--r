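# Parameter containers: kinetic constants, stoichiometry, inoculum handling.

.param_names <- c(paste0("k", 1:12), "cor_bio", "cor_NPN", "cor_X",
                  "y1_max", "y4_max", "y5_max")
.free_names <- .param_names[1:15]
.state_names <- paste0("y", 1:6)

#' Kinetic parameter set for the six-state fermentation model
#'
#' Bundles the twelve rate constants `k1`...`k12`, the three correction
#' factors `cor_bio`, `cor_NPN`, `cor_X`, and the saturation maxima
#' `y1_max`, `y4_max`, `y5_max` governing one fermentation batch.
#'
#' Units (time in hours throughout): `k1` maximum specific growth rate
#' (1/hr); `k2` Monod half-saturation constant (g N/100 g); `k3` lag-decay
#' rate (1/hr); `k4` growth-associated nonprotein-nitrogen yield
#' (dimensionless); `k5` non-growth NPN rate constant (1/hr); `k6`
#' growth-associated lactic-acid yield (g/g); `k7` non-growth lactic-acid
#' rate (g/100 g/hr); `k8`, `k9` the analogous formic-acid terms; `k10`
#' glucose-to-biomass uptake yield (g/g); `k11` glucose-to-lactate uptake
#' rate (g/100 g/hr); `k12` cell-lysis rate (1/hr); `cor_bio`, `cor_NPN`
#' dimensionless correction factors; `cor_X` first-order protein-loss rate
#' (1/hr); maxima in the units of their respective states.
#'
#' @param ... named parameter values; every name must be one of the
#'   eighteen listed above.
#' @param base optional `ferm_params` object (or named vector) supplying
#'   values not given in `...`.
#' @return A named numeric vector of class `ferm_params`.
#' @examples
#' p <- ferm_params(base = batch_params("control"), k6 = 0.5)
#' p["k6"]
#' @export
ferm_params <- function(..., base = NULL) {
  vals <- c(...)
  if (is.null(base)) {
    x <- setNames(rep(NA_real_, length(.param_names)), .param_names)
  } else {
    x <- as_ferm_params(base, validate = FALSE)
  }
  if (length(vals)) {
    bad <- setdiff(names(vals), .param_names)
    if (length(bad)) stop("unknown parameter name(s): ", paste(bad, collapse = ", "))
    x[names(vals)] <- vals
  }
  validate_params(x)
  structure(x, class = "ferm_params")
}

as_ferm_params <- function(x, validate = TRUE) {
  x <- unclass(x)
  if (is.list(x)) x <- unlist(x)
  if (is.null(names(x)) && length(x) == length(.param_names)) names(x) <- .param_names
  miss <- setdiff(.param_names, names(x))
  if (length(miss)) stop("missing parameter(s): ", paste(miss, collapse = ", "))
  x <- x[.param_names]
  if (validate) validate_params(x)
  structure(x, class = "ferm_params")
}

validate_params <- function(x) {
  if (anyNA(x)) stop("parameter(s) not set: ",
                     paste(names(x)[is.na(x)], collapse = ", "))
  if (any(x < 0)) stop("parameters must be nonnegative; offending: ",
                       paste(names(x)[x < 0], collapse = ", "))
  maxima <- c("y1_max", "y4_max", "y5_max")
  if (any(x[maxima] <= 0)) stop("saturation maxima must be strictly positive")
  invisible(x)
}

#' @export
print.ferm_params <- function(x, ...) {
  cat("Fermentation kinetic parameters:\n")
  print(signif(unclass(x), 4))
  invisible(x)
}

#' Fitted parameter sets for the two study batches
#'
#' Returns the reported parameter estimates for either the spontaneously
#' fermented control batch or the batch inoculated with *Pediococcus
#' acidilactici*, together with the saturation maxima used throughout the
#' package: `y1_max` corresponding to a plateau count of 1e9 CFU/g at the
#' batch's CFU-to-mass conversion factor, `y4_max` = 1.5 and `y5_max` = 0.2
#' g/100 g.
#'
#' @param batch `"control"` or `"p_acidilactici"`.
#' @return A `ferm_params` object.
#' @examples
#' batch_params("control")["k6"]
#' @export
batch_params <- function(batch = c("control", "p_acidilactici")) {
  batch <- match.arg(batch)
  if (batch == "control") {
    ferm_params(
      k1 = 0.330, k2 = 0.061, k3 = 0.142, k4 = 3.7e-5, k5 = 1.517e-5,
      k6 = 0.414, k7 = 0.064, k8 = 0.013, k9 = 1.458e-3, k10 = 9.855e-3,
      k11 = 0.101, k12 = 1.7e-3,
      cor_bio = 1.118, cor_NPN = 0.832, cor_X = 0.025,
      y1_max = cfu_to_mass(1e9, conversion = 2e-12),
      y4_max = 1.5, y5_max = 0.2)
  } else {
    ferm_params(
      k1 = 0.244, k2 = 0.088, k3 = 0.141, k4 = 4.64e-4, k5 = 1.275e-5,
      k6 = 1.112e-3, k7 = 0.095, k8 = 2.623e-4, k9 = 1.7498e-3,
      k10 = 6.674e-3, k11 = 1.280, k12 = 1.9e-3,
      cor_bio = 1.094, cor_NPN = 0.723, cor_X = 0.046,
      y1_max = cfu_to_mass(1e9, conversion = 3e-12),
      y4_max = 1.5, y5_max = 0.2)
  }
}

#' Stoichiometric constants coupling biomass, protein and NPN nitrogen
#'
#' Nitrogen bookkeeping for the protein balance: the nitrogen mass
#' fractions `N*AW_N/MW` of the biomass formula unit and of the average
#' nonprotein-nitrogen (NPN) unit convert biomass formation and NPN
#' release into protein-nitrogen equivalents. Defaults use the standard
#' microbial biomass formula CH1.8O0.5N0.2 and an average free amino acid
#' (1 N, MW 120) for NPN.
#'
#' @param N_bio nitrogen atoms per biomass formula unit.
#' @param MW_bio formula weight of the biomass unit (g/mol).
#' @param N_NPN nitrogen atoms per NPN unit.
#' @param MW_NPN formula weight of the NPN unit (g/mol).
#' @param AW_N atomic weight of nitrogen (g/mol).
#' @return An object of class `ferm_stoich` with derived nitrogen mass
#'   fractions `frac_bio` and `frac_npn`.
#' @examples
#' stoichiometry()$frac_bio
#' @export
stoichiometry <- function(N_bio = 0.2, MW_bio = 24.63, N_NPN = 1,
                          MW_NPN = 120, AW_N = 14.007) {
  vals <- c(N_bio = N_bio, MW_bio = MW_bio, N_NPN = N_NPN,
            MW_NPN = MW_NPN, AW_N = AW_N)
  if (any(vals <= 0)) stop("stoichiometric constants must be positive")
  s <- list(N_bio = N_bio, MW_bio = MW_bio, N_NPN = N_NPN,
            MW_NPN = MW_NPN, AW_N = AW_N,
            frac_bio = N_bio * AW_N / MW_bio,
            frac_npn = N_NPN * AW_N / MW_NPN)
  if (s$frac_bio <= 0 || s$frac_bio >= 1 || s$frac_npn <= 0 || s$frac_npn >= 1)
    stop("derived nitrogen mass fractions must lie in (0, 1)")
  structure(s, class = "ferm_stoich")
}

#' Inoculum specification
#'
#' Records the starter-culture dose and the per-cell mass used to convert
#' plate counts into dry biomass. The conversion factor depends on cell
#' morphology: 2e-12 g/CFU for doublet-forming LAB, 3e-12 g/CFU for the
#' doublets-plus-tetrads morphology of *P. acidilactici*.
#'
#' @param dose inoculum density (CFU/g sausage).
#' @param morphology `"doublets"` or `"doublets+tetrads"`.
#' @param conversion cell mass per CFU (g/CFU); overrides the
#'   morphology-based default.
#' @return A list of class `inoculum_spec`.
#' @examples
#' inoculum_spec(morphology = "doublets+tetrads")$conversion
#' @export
inoculum_spec <- function(dose = 2e7,
                          morphology = c("doublets", "doublets+tetrads"),
                          conversion = NULL) {
  morphology <- match.arg(morphology)
  if (is.null(conversion))
    conversion <- if (morphology == "doublets") 2e-12 else 3e-12
  if (dose <= 0 || conversion <= 0) stop("dose and conversion must be positive")
  structure(list(dose = dose, conversion = conversion,
                 morphology_label = morphology),
            class = "inoculum_spec")
}

#' Convert plate counts to biomass concentration (and back)
#'
#' `cfu_to_mass()` converts a viable count (CFU/g sausage) to dry-cell
#' mass in the per-100-g convention used by the model state `y1`;
#' `mass_to_cfu()` is its inverse.
#'
#' @param count viable count (CFU/g sausage); must be nonnegative.
#' @param mass biomass concentration (g dry cells/100 g sausage).
#' @param conversion cell mass per CFU (g/CFU), or an [inoculum_spec()].
#' @return Numeric, g/100 g (or CFU/g for the inverse).
#' @examples
#' cfu_to_mass(2e7, conversion = 3e-12) # 6e-3 g/100 g
#' @export
cfu_to_mass <- function(count, conversion = 2e-12) {
  if (inherits(conversion, "inoculum_spec")) conversion <- conversion$conversion
  if (any(count < 0)) stop("count must be nonnegative")
  if (conversion <= 0) stop("conversion must be positive")
  count * conversion * 100
}

#' @rdname cfu_to_mass
#' @export
mass_to_cfu <- function(mass, conversion = 2e-12) {
  if (inherits(conversion, "inoculum_spec")) conversion <- conversion$conversion
  if (any(mass < 0)) stop("mass must be nonnegative")
  if (conversion <= 0) stop("conversion must be positive")
  mass / 100 / conversion
}

# flat numeric vector of length 20 handed to the compiled core
pack_params <- function(params, stoich) {
  c(unclass(params), stoich$frac_bio, stoich$frac_npn)
}

#' Read and write parameter sets as JSON
#'
#' Parameter sets and stoichiometric constants are serialised as a flat
#' JSON object keyed by the symbol names (`k1`...`k12`, `cor_bio`,
#' `cor_NPN`, `cor_X`, `y1_max`, `y4_max`, `y5_max`, and optionally the
#' stoichiometry fields).
#'
#' @param params a `ferm_params` object.
#' @param path file path.
#' @param stoich optional `ferm_stoich` to store alongside.
#' @return `read_params()` returns a `ferm_params`; if the file carries
#'   stoichiometry fields they are attached as attribute `"stoich"`.
#' @export
write_params <- function(params, path, stoich = NULL) {
  params <- as_ferm_params(params)
  out <- as.list(unclass(params))
  if (!is.null(stoich))
    out <- c(out, stoich[c("N_bio", "MW_bio", "N_NPN", "MW_NPN", "AW_N")])
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_params
#' @export
read_params <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  p <- as_ferm_params(unlist(x[.param_names]))
  sf <- c("N_bio", "MW_bio", "N_NPN", "MW_NPN", "AW_N")
  if (all(sf %in% names(x)))
    attr(p, "stoich") <- do.call(stoichiometry, x[sf])
  p
}
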