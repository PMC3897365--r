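#' Model parameter set
#'
#' Constructs and validates the full parameter set of the model. All sixteen
#' parameters must be supplied (see [default_parameters()] for the canonical
#' fitted values for the 4T1 mouse mammary carcinoma system). Units are
#' mm^3, mg and days throughout; one cell = 1e-6 mm^3.
#'
#' @param a_p,b_p,d_p primary-tumor proliferation rate (day^-1), angiogenic
#'   stimulation (day^-1) and local angiogenic inhibition (mm^-2 day^-1).
#' @param a,b,d the same three growth parameters for metastases.
#' @param m colonization coefficient of the dissemination law
#'   `beta(V) = m * V^alpha` (mm^-3alpha day^-1).
#' @param alpha fractal exponent of the dissemination law, in `[0, 1]`
#'   (one third of the fractal dimension of the tumor vasculature).
#' @param p inhibitor production rate per unit tumor volume
#'   (mg mm^-3 day^-1).
#' @param k inhibitor elimination rate from the circulation (day^-1).
#' @param e inhibitor efficacy (mg^-1 day^-1).
#' @param V0 newborn metastasis volume, one cell (mm^3).
#' @param K0 newborn metastasis carrying capacity (mm^3).
#' @param Vm emission threshold volume: lesions below `Vm` do not seed
#'   metastases (mm^3).
#' @param D2 inhibitor diffusion coefficient inside a tumor (mm^2 day^-1).
#' @param Vd inhibitor distribution volume of the host (mm^3).
#' @return An object of class `"sia_parameters"` (a named list).
#' @seealso [default_parameters()], [load_parameters()],
#'   [derive_local_inhibition()]
#' @export
#' @examples
#' pars <- default_parameters()
#' pars$b / pars$d # sets the no-SIA equilibrium volume (b/d)^(3/2)
model_parameters <- function(a_p, b_p, d_p, a, b, d, m, alpha, p, k, e,
                             V0, K0, Vm, D2, Vd) {
  pars <- list(a_p = a_p, b_p = b_p, d_p = d_p, a = a, b = b, d = d,
               m = m, alpha = alpha, p = p, k = k, e = e,
               V0 = V0, K0 = K0, Vm = Vm, D2 = D2, Vd = Vd)
  validate_parameters(pars)
}

.param_keys <- c("a_p", "b_p", "d_p", "a", "b", "d", "m", "alpha",
                 "p", "k", "e", "V0", "K0", "Vm", "D2", "Vd")

validate_parameters <- function(pars) {
  missing <- setdiff(.param_keys, names(pars))
  if (length(missing) > 0L)
    stop("missing parameter(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  unknown <- setdiff(names(pars), .param_keys)
  if (length(unknown) > 0L)
    stop("unknown parameter(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  pars <- pars[.param_keys]
  for (key in .param_keys) {
    val <- pars[[key]]
    if (!is.numeric(val) || length(val) != 1L || !is.finite(val))
      stop("parameter '", key, "' must be a single finite number",
           call. = FALSE)
  }
  strict_pos <- c("a_p", "b_p", "a", "b", "k", "V0", "K0", "Vm", "D2", "Vd")
  for (key in strict_pos)
    if (pars[[key]] <= 0)
      stop("parameter '", key, "' must be > 0", call. = FALSE)
  non_neg <- c("d_p", "d", "m", "p", "e")
  for (key in non_neg)
    if (pars[[key]] < 0)
      stop("parameter '", key, "' must be >= 0", call. = FALSE)
  if (pars$alpha < 0 || pars$alpha > 1)
    stop("parameter 'alpha' must lie in [0, 1]", call. = FALSE)
  if (pars$V0 > pars$Vm)
    stop("'V0' must not exceed the emission threshold 'Vm'", call. = FALSE)
  structure(pars, class = "sia_parameters")
}

#' Canonical fitted parameter set (4T1 mouse mammary carcinoma)
#'
#' The parameter values estimated for the 4T1 system: growth parameters
#' fitted to primary-tumor growth curves and metastatic endpoint data,
#' inhibitor parameters taken from angiostatin pharmacology in a 20 g
#' mouse, and the local inhibition coefficient `d` derived from the
#' intra-tumor diffusion analysis (see [derive_local_inhibition()]).
#'
#' @return An `"sia_parameters"` object.
#' @export
#' @examples
#' default_parameters()
default_parameters <- function() {
  model_parameters(
    a_p = 0.154, b_p = 16.7, d_p = 0.0717,
    a = 0.154, b = 12.5, d = 0.0717,
    m = 0.0229, alpha = 2 / 3,
    p = 8.3e-6, k = 0.38, e = 7.5,
    V0 = 1e-6, K0 = 1, Vm = 1,
    D2 = 0.156, Vd = 7000
  )
}

#' Read and write model parameter files
#'
#' Parameter sets are serialized as flat JSON or YAML maps whose keys are
#' the sixteen canonical parameter names. Unknown keys are rejected and all
#' domain constraints are enforced on read. The format is inferred from the
#' file extension (`.json`, `.yaml`/`.yml`).
#'
#' @param path file path.
#' @return `load_parameters()` returns an `"sia_parameters"` object;
#'   `write_parameters()` returns `path` invisibly.
#' @export
#' @examples
#' path <- system.file("extdata", "params_4t1.json", package = "angiomet")
#' load_parameters(path)
load_parameters <- function(path) {
  if (!file.exists(path)) stop("parameter file not found: ", path,
                               call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    json = jsonlite::read_json(path, simplifyVector = TRUE),
    yaml = ,
    yml = yaml::read_yaml(path),
    stop("unsupported parameter file extension: '", ext, "'", call. = FALSE)
  )
  raw <- lapply(as.list(raw), as.numeric)
  validate_parameters(raw)
}

#' @param pars an `"sia_parameters"` object.
#' @rdname load_parameters
#' @export
write_parameters <- function(pars, path) {
  pars <- validate_parameters(unclass(pars))
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    jsonlite::write_json(unclass(pars), path, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  } else if (ext %in% c("yaml", "yml")) {
    yaml::write_yaml(unclass(pars), path, precision = 15L)
  } else {
    stop("unsupported parameter file extension: '", ext, "'", call. = FALSE)
  }
  invisible(path)
}

#' @export
print.sia_parameters <- function(x, ...) {
  cat("Model parameters (mm^3 / mg / day):\n")
  vals <- vapply(x, function(v) format(v, digits = 6), character(1))
  cat(paste0("  ", format(names(vals), width = 6), " = ", vals,
             collapse = "\n"), "\n")
  invisible(x)
}
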