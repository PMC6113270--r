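#' Model parameters for the seagrass-lucinid system
#'
#' Constructs the validated parameter set of the seagrass-sulfide-organic
#' matter-lucinid model. Defaults are the empirically calibrated values for
#' the *Zostera noltii* / *Loripes lucinalis* system of the Banc d'Arguin
#' intertidal flats. The organic-matter-to-sulfide conversion `C_om` is, by
#' calibration, coupled to the shoots-to-organic-matter conversion as
#' `C_om = 0.01 / C_z`; when `C_om` is not supplied it is derived from `C_z`,
#' but it can be set independently (the sensitivity analysis varies every
#' parameter on its own).
#'
#' @param Z_max Seagrass carrying capacity, shoots m^-2.
#' @param r Seagrass relative growth rate, day^-1.
#' @param m_s Maximum sulfide-driven seagrass mortality rate, day^-1.
#' @param m_n Natural (background) seagrass mortality rate, day^-1; used
#'   throughout as a proxy for low-tide desiccation stress.
#' @param C_om Conversion of sediment organic matter to sulfide production,
#'   umol L^-1 %^-1 day^-1. Default `0.01 / C_z`.
#' @param C_s Sulfide uptake per *Loripes* individual, m^2 ind^-1 day^-1.
#' @param e_s Abiotic sulfide loss rate (oxidation, outwelling), day^-1.
#' @param C_z Conversion of dead shoots to organic matter,
#'   percent m^2 shoots^-1.
#' @param e_m Organic matter loss rate (decomposition, export), day^-1.
#' @param S_min Sulfide concentration at toxicity onset, umol L^-1.
#' @param S_max Sulfide concentration of full toxicity, umol L^-1.
#' @param r_L *Loripes* growth rate, ind m^-2 day^-1.
#' @param L_max *Loripes* carrying capacity, ind m^-2.
#' @param m_L *Loripes* natural mortality rate, day^-1.
#'
#' @return An object of class `seagrass_params`: a named list of the 14
#'   parameters above.
#' @examples
#' p <- seagrass_params()
#' p$C_om * p$C_z  # the calibrated coupling, 0.01
#' @export
seagrass_params <- function(Z_max = 8000,
                            r = 0.35,
                            m_s = 0.5,
                            m_n = 0.007,
                            C_om = NULL,
                            C_s = 0.0027,
                            e_s = 0.29,
                            C_z = 2.017e-6,
                            e_m = 0.0009,
                            S_min = 200,
                            S_max = 1000,
                            r_L = 26,
                            L_max = 4900,
                            m_L = 0.002) {
  if (is.null(C_om)) C_om <- 0.01 / C_z
  p <- list(Z_max = Z_max, r = r, m_s = m_s, m_n = m_n, C_om = C_om,
            C_s = C_s, e_s = e_s, C_z = C_z, e_m = e_m, S_min = S_min,
            S_max = S_max, r_L = r_L, L_max = L_max, m_L = m_L)
  validate_params(p)
  structure(p, class = "seagrass_params")
}

#' @rdname seagrass_params
#' @param x A `seagrass_params` object (or, for `as_seagrass_params`, a named
#'   list or named numeric vector of parameter values).
#' @export
as_seagrass_params <- function(x) {
  if (inherits(x, "seagrass_params")) return(x)
  x <- as.list(x)
  unknown <- setdiff(names(x), param_names())
  if (length(unknown))
    stop("unknown parameter name(s): ", paste(unknown, collapse = ", "))
  do.call(seagrass_params, x)
}

param_names <- function() {
  c("Z_max", "r", "m_s", "m_n", "C_om", "C_s", "e_s",
    "C_z", "e_m", "S_min", "S_max", "r_L", "L_max", "m_L")
}

validate_params <- function(p) {
  for (nm in param_names()) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("parameter '", nm, "' must be a single finite number")
    if (v < 0)
      stop("parameter '", nm, "' must be non-negative (got ", v, ")")
  }
  if (p$S_max <= p$S_min)
    stop("S_max must exceed S_min (toxicity ramp would be degenerate)")
  if (p$S_min <= 0) stop("S_min must be positive")
  if (p$Z_max <= 0) stop("Z_max must be positive")
  if (p$L_max <= 0) stop("L_max must be positive")
  invisible(p)
}

#' Replace one parameter in a parameter set
#'
#' Convenience used by the scans: returns a copy of `p` with the named
#' parameter set to `value` (revalidated).
#'
#' @param p A [seagrass_params()] object.
#' @param name Parameter name, one of the 14 model parameters.
#' @param value New value.
#' @return A new `seagrass_params` object.
#' @export
set_param <- function(p, name, value) {
  p <- as_seagrass_params(p)
  if (!name %in% param_names()) stop("unknown parameter name: ", name)
  p[[name]] <- value
  validate_params(p)
  structure(p, class = "seagrass_params")
}

#' @export
print.seagrass_params <- function(x, ...) {
  units <- c(Z_max = "shoots m-2", r = "day-1", m_s = "day-1", m_n = "day-1",
             C_om = "umol L-1 %-1 day-1", C_s = "m2 ind-1 day-1",
             e_s = "day-1", C_z = "% m2 shoots-1", e_m = "day-1",
             S_min = "umol L-1", S_max = "umol L-1",
             r_L = "ind m-2 day-1", L_max = "ind m-2", m_L = "day-1")
  cat("Seagrass-lucinid model parameters:\n")
  for (nm in param_names())
    cat(sprintf("  %-6s %-12.6g %s\n", nm, x[[nm]], units[[nm]]))
  invisible(x)
}

# Parameter vector in the fixed order expected by the compiled RHS
# (p[15] is the mutualism flag).
rhs_parms <- function(p, mutualism = TRUE) {
  c(unlist(p[param_names()], use.names = FALSE), as.numeric(isTRUE(mutualism)))
}

#' Read or write a parameter/config file
#'
#' Flat key:value configuration files in YAML (default) or JSON, with keys
#' named exactly as the model symbols (`Z_max`, `r`, `m_s`, `m_n`, `C_om`,
#' `C_s`, `e_s`, `C_z`, `e_m`, `S_min`, `S_max`, `r_L`, `L_max`, `m_L`).
#' Keys that are absent fall back to the defaults of [seagrass_params()];
#' unknown keys are an error. Files ending in `.json` are treated as JSON,
#' anything else as YAML.
#'
#' @param path File path.
#' @param p For `write_model_config`, a [seagrass_params()] object.
#' @return `read_model_config` returns a `seagrass_params` object;
#'   `write_model_config` returns `path` invisibly.
#' @export
read_model_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  vals <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (is.null(vals)) vals <- list()
  as_seagrass_params(vals)
}

#' @rdname read_model_config
#' @export
write_model_config <- function(p, path) {
  p <- as_seagrass_params(p)
  vals <- lapply(unclass(p), function(v) unname(v))
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(vals, path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(vals, path)
  }
  invisible(path)
}
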