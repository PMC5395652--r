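#' Pharmacokinetic parameters of the TMDD model
#'
#' Constructs the parameter set of the two-compartment target-mediated
#' drug disposition model.  Defaults are the published exenatide values
#' (Gao-Jusko model).  All rates are per minute; concentrations are in
#' pM; `V_c` is the central volume of distribution per kg bodyweight in
#' ml/kg (converted to L/kg internally so that `u / V_c` with `u` in
#' pmol/min/kg yields pM/min).
#'
#' @param k_el elimination rate constant (1/min)
#' @param k_pt,k_tp intercompartmental rate constants (1/min)
#' @param V_c central volume of distribution (ml/kg)
#' @param k_on second-order binding constant (1/pM/min)
#' @param k_off first-order dissociation constant (1/min)
#' @param k_int internalization rate constant of the drug-receptor
#'   complex (1/min)
#' @param R_tot total receptor concentration (pM)
#' @return an object of class `pk_parameters` (named list)
#' @export
#' @examples
#' p <- pk_parameters()
#' steady_state_concentration(0.05, p)
pk_parameters <- function(k_el = 0.013, k_pt = 0.0685, k_tp = 0.0846,
                          V_c = 111, k_on = 0.000411, k_off = 0.566,
                          k_int = 0.00342, R_tot = 1240) {
  p <- list(k_el = k_el, k_pt = k_pt, k_tp = k_tp, V_c = V_c,
            k_on = k_on, k_off = k_off, k_int = k_int, R_tot = R_tot)
  vals <- unlist(p)
  if (any(!is.finite(vals)) || any(vals < 0))
    stop("all PK parameters must be finite and non-negative")
  if (any(vals[c("k_el", "V_c")] <= 0))
    stop("k_el and V_c must be strictly positive")
  structure(p, class = "pk_parameters")
}

#' @export
print.pk_parameters <- function(x, ...) {
  cat("TMDD pharmacokinetic parameters:\n")
  for (nm in names(x)) cat(sprintf("  %-6s %g\n", nm, x[[nm]]))
  invisible(x)
}

# central volume in L/kg, the unit in which the ODE is integrated
vc_L <- function(params) params$V_c / 1000

# parameter vector in the order the compiled right-hand side expects
pk_vector <- function(params) {
  c(params$k_el, params$k_pt, params$k_tp, vc_L(params),
    params$k_on, params$k_off, params$k_int, params$R_tot)
}

#' Load PK parameters from a YAML or JSON config file
#'
#' Unknown fields are ignored; missing fields keep their defaults.
#'
#' @param path path to a YAML (`.yml`/`.yaml`) or JSON file whose
#'   top-level `pk` block (or the file root) holds fields named as in
#'   [pk_parameters()]
#' @return a `pk_parameters` object
#' @export
load_pk_parameters <- function(path) {
  cfg <- read_config_file(path)
  if (!is.null(cfg$pk)) cfg <- cfg$pk
  keep <- intersect(names(cfg), names(formals(pk_parameters)))
  do.call(pk_parameters, cfg[keep])
}

read_config_file <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path)
  else
    jsonlite::read_json(path, simplifyVector = TRUE)
}
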