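#' Read a plain-text key-value configuration file
#'
#' The package-wide configuration format is flat `key = value` lines
#' (also `key: value`); blank lines and `#` comments are ignored. Keys are
#' either model parameters (any field of [wound_params()]), scenario keys
#' (`scenario` = `"wound"` or `"perturbation"`, `k`, `amp_N`, `amp_rho`,
#' `amp_v`, `amp_eps`, `domain_length`, `wound_length`, `ramp_length`,
#' `c_w`, `N_w`, `rho_w`), or solver keys (`n`, `t_end`, `dt`, `picard_tol`,
#' `picard_max`, `lumping`, `boundary`, `eps_bar`, `seed`). Unknown keys are
#' rejected with an error naming the key. An empty file yields the full
#' defaults (reference parameters, 0.5-day steps, 500 elements on the half
#' domain).
#'
#' @param path configuration file path.
#' @return An object of class `run_config`: list with `params`
#'   ([wound_params()]), `scenario`, `solver` settings and the raw key-value
#'   pairs (`raw`) echoed into outputs for provenance.
#' @export
load_config <- function(path) {
  raw <- list()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    lines <- readLines(path, warn = FALSE)
    lines <- sub("#.*$", "", lines)
    lines <- trimws(lines)
    lines <- lines[nzchar(lines)]
    for (ln in lines) {
      m <- regmatches(ln, regexec("^([A-Za-z_][A-Za-z0-9_]*)\\s*[=:]\\s*(.+)$",
                                  ln))[[1]]
      if (length(m) != 3)
        stop("cannot parse config line: '", ln, "'")
      key <- m[2]; val <- trimws(m[3])
      num <- suppressWarnings(as.numeric(val))
      raw[[key]] <- if (!is.na(num)) num else val
    }
  }
  param_keys <- names(wound_params())    # full field list
  scen_keys <- c("scenario", "k", "amp_N", "amp_rho", "amp_v", "amp_eps",
                 "domain_length", "wound_length", "ramp_length",
                 "c_w", "N_w", "rho_w")
  solver_keys <- c("n", "t_end", "dt", "picard_tol", "picard_max",
                   "lumping", "boundary", "eps_bar", "seed")
  unknown <- setdiff(names(raw), c(param_keys, scen_keys, solver_keys))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  pov <- raw[intersect(names(raw), param_keys)]
  params <- do.call(wound_params, pov)
  getd <- function(key, default) if (!is.null(raw[[key]])) raw[[key]] else default
  scen_type <- getd("scenario", "perturbation")
  if (!scen_type %in% c("wound", "perturbation"))
    stop("scenario must be 'wound' or 'perturbation'")
  scenario <- if (scen_type == "wound")
    wound_scenario(domain_length = getd("domain_length", 10),
                   wound_length = getd("wound_length", 4),
                   ramp_length = getd("ramp_length", 1),
                   c_w = getd("c_w", 1e-8), N_w = getd("N_w", 2000),
                   rho_w = getd("rho_w", 0.01125))
  else
    perturbation_scenario(k = getd("k", 1), amp_N = getd("amp_N", 10),
                          amp_rho = getd("amp_rho", 1e-2),
                          amp_v = getd("amp_v", 0.05),
                          amp_eps = getd("amp_eps", 0.5))
  solver <- list(n = getd("n", if (scen_type == "wound") 100 else 500),
                 t_end = getd("t_end", 400),
                 dt = getd("dt", 0.5),
                 picard_tol = getd("picard_tol", 1e-8),
                 picard_max = getd("picard_max", 25),
                 lumping = !identical(getd("lumping", 1), 0),
                 eps_bar = getd("eps_bar", 0),
                 seed = getd("seed", NA))
  structure(list(params = params, scenario = scenario, solver = solver,
                 raw = raw), class = "run_config")
}

#' Write parameters to a key-value config or JSON file
#'
#' @param params a [wound_params()] object.
#' @param path output path; a `.json` extension selects JSON, anything else
#'   the plain-text key-value format.
#' @return The path, invisibly.
#' @export
write_params <- function(params, path) {
  stopifnot(inherits(params, "wound_params"))
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(unclass(params), path, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  } else {
    writeLines(sprintf("%s = %.17g", names(params),
                       unlist(params, use.names = FALSE)), path)
  }
  invisible(path)
}

#' Write run outputs and a manifest
#'
#' Writes each table as CSV and the summary as JSON into `dir`, together
#' with a `manifest.json` listing the files, their MD5 hashes and the echoed
#' configuration, so that a run is fully reproducible from its output
#' directory (all pipelines are deterministic).
#'
#' @param summary a list of scalar results (written as `summary.json`).
#' @param tables named list of data frames (each written as `<name>.csv`
#'   with fixed 15-significant-digit formatting, bit-stable across runs).
#' @param dir output directory (created if needed).
#' @param config optional `run_config` (or any list) echoed into the
#'   manifest.
#' @return The manifest, invisibly.
#' @export
write_outputs <- function(summary, tables = list(), dir, config = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  if (length(summary)) {
    sp <- file.path(dir, "summary.json")
    jsonlite::write_json(summary, sp, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    files <- c(files, sp)
  }
  for (nm in names(tables)) {
    tp <- file.path(dir, paste0(nm, ".csv"))
    df <- tables[[nm]]
    num <- vapply(df, is.numeric, TRUE)
    df[num] <- lapply(df[num], function(z) signif(z, 15))
    utils::write.csv(df, tp, row.names = FALSE)
    files <- c(files, tp)
  }
  manifest <- list(
    files = if (length(files))
      data.frame(file = basename(files),
                 md5 = unname(tools::md5sum(files)),
                 stringsAsFactors = FALSE)
    else data.frame(file = character(0), md5 = character(0)),
    config = if (inherits(config, "run_config")) config$raw else config)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
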