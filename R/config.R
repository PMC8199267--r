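#' Construct a docking scenario
#'
#' A scenario bundles everything one docking run needs: the scoring
#' function and its parameters, the resolved ACO parameters, the binding
#' sphere and the discretization steps.
#'
#' @param name unique identifier.
#' @param scoring_function \code{"chemplp"}, \code{"plp"} or \code{"plp95"}.
#' @param sphere a \code{\link{docking_sphere}}.
#' @param search_speed 1, 2 or 4.
#' @param aco_overrides named list of explicit ACO settings (see
#'   \code{\link{resolve_defaults}}).
#' @param scoring_overrides named list passed to \code{\link{scoring_params}}.
#' @param angular_step,linear_step discretization steps (degrees / Angstrom).
#' @param use_local_search logical; simplex refinement of every ant.
#' @param sample_within \code{"uniform"} or \code{"midpoint"}.
#' @param receptor_path optional path to the receptor MOL2.
#' @return object of class \code{docking_scenario}.
#' @export
docking_scenario <- function(name, scoring_function = "chemplp",
                             sphere = docking_sphere(c(0, 0, 0), 13),
                             search_speed = 4, aco_overrides = NULL,
                             scoring_overrides = NULL,
                             angular_step = 1, linear_step = 0.5,
                             use_local_search = TRUE,
                             sample_within = "uniform",
                             receptor_path = NULL) {
  structure(list(
    name = name,
    scoring_function = scoring_function,
    params = scoring_params(scoring_function, overrides = scoring_overrides),
    aco = resolve_defaults(scoring_function, search_speed,
                           overrides = aco_overrides),
    sphere = sphere,
    angular_step = angular_step, linear_step = linear_step,
    use_local_search = use_local_search,
    sample_within = sample_within,
    receptor_path = receptor_path),
    class = "docking_scenario")
}

#' Parse a per-scenario docking configuration file
#'
#' Whitespace-separated \code{keyword value ...} lines with \code{#}
#' comments, using the conventional docking-config keywords:
#' \code{scoring_function}, \code{search_speed}, \code{aco_ants},
#' \code{aco_evap}, \code{aco_sigma}, \code{bindingsite_center x y z},
#' \code{bindingsite_radius r}, \code{protein_file}, \code{output_dir}.
#' Explicitly set ACO values override the preset defaults.
#'
#' @param path file path (or \code{text} as a string).
#' @param text configuration text, exclusive with \code{path}.
#' @param name scenario name (defaults to the config's directory name).
#' @return a \code{\link{docking_scenario}}.
#' @export
parse_scenario_config <- function(path = NULL, text = NULL, name = NULL) {
  if (is.null(text) == is.null(path)) {
    stop("supply exactly one of 'path' or 'text'", call. = FALSE)
  }
  lines <- if (!is.null(path)) readLines(path, warn = FALSE)
           else unlist(strsplit(text, "\n", fixed = TRUE))
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "\\s+")
  keys <- vapply(kv, `[[`, "", 1L)
  vals <- lapply(kv, function(t) t[-1])
  get1 <- function(k, default = NULL) {
    i <- match(k, keys)
    if (is.na(i)) default else vals[[i]]
  }
  sf <- get1("scoring_function", "chemplp")[1]
  if (!sf %in% c("chemplp", "plp", "plp95")) {
    stop(sprintf("unknown scoring_function '%s'", sf), call. = FALSE)
  }
  speed <- as.integer(get1("search_speed", "4")[1])
  ctr <- as.numeric(get1("bindingsite_center", c("0", "0", "0")))
  rad <- as.numeric(get1("bindingsite_radius", "13")[1])
  ov <- list()
  if (!is.null(get1("aco_ants"))) ov$n_ants <- as.integer(get1("aco_ants")[1])
  if (!is.null(get1("aco_evap"))) ov$rho <- as.numeric(get1("aco_evap")[1])
  if (!is.null(get1("aco_sigma"))) ov$sigma <- as.numeric(get1("aco_sigma")[1])
  if (!is.null(get1("aco_iterations"))) {
    ov$iterations <- as.integer(get1("aco_iterations")[1])
  }
  if (!is.null(get1("aco_ls_budget"))) {
    ov$ls_budget <- as.integer(get1("aco_ls_budget")[1])
  }
  if (is.null(name)) {
    name <- if (!is.null(path)) basename(dirname(normalizePath(path, mustWork = FALSE)))
            else "scenario"
  }
  docking_scenario(
    name = name, scoring_function = sf,
    sphere = docking_sphere(ctr, rad),
    search_speed = speed,
    aco_overrides = if (length(ov)) ov else NULL,
    angular_step = as.numeric(get1("angular_step", "1")[1]),
    linear_step = as.numeric(get1("linear_step", "0.5")[1]),
    receptor_path = if (!is.null(get1("protein_file"))) get1("protein_file")[1] else NULL)
}

#' Parse a virtual-screening control file
#'
#' \code{key=value} lines with \code{#} comments.  Required keys:
#' \code{ligand_library_format} (\code{PDBQT} or \code{MOL2}),
#' \code{docking_scenario_names} (colon- or comma-separated list),
#' \code{library_root}, \code{output_root}.  Optional: \code{workers}
#' (default 1), \code{seed} (default 1), \code{input_files} (folder holding
#' one \code{<scenario>/config.txt} per scenario; default
#' \code{input-files} next to the control file), \code{receptor}
#' (MOL2 path used for every scenario), \code{use_local_scratch}
#' (\code{yes}/\code{no}).  Unknown keys warn but do not fail.
#'
#' @param path control file path (or \code{text}).
#' @param text control file text, exclusive with \code{path}.
#' @return object of class \code{control_file} with resolved
#'   \code{\link{docking_scenario}} objects.
#' @export
parse_control_file <- function(path = NULL, text = NULL) {
  if (is.null(text) == is.null(path)) {
    stop("supply exactly one of 'path' or 'text'", call. = FALSE)
  }
  base_dir <- if (!is.null(path)) dirname(normalizePath(path)) else getwd()
  lines <- if (!is.null(path)) readLines(path, warn = FALSE)
           else unlist(strsplit(text, "\n", fixed = TRUE))
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (!all(grepl("=", lines, fixed = TRUE))) {
    stop("control file lines must be key=value", call. = FALSE)
  }
  keys <- trimws(sub("=.*$", "", lines))
  vals <- trimws(sub("^[^=]*=", "", lines))
  known <- c("ligand_library_format", "docking_scenario_names", "workers",
             "seed", "library_root", "output_root", "input_files",
             "receptor", "use_local_scratch")
  unknown <- setdiff(keys, known)
  if (length(unknown)) {
    warning("ignoring unknown control-file key(s): ",
            paste(unknown, collapse = ", "), call. = FALSE)
  }
  get1 <- function(k, default = NULL, required = FALSE) {
    i <- match(k, keys)
    if (is.na(i)) {
      if (required) stop(sprintf("missing required control-file key '%s'", k),
                         call. = FALSE)
      default
    } else vals[i]
  }
  fmt <- get1("ligand_library_format", required = TRUE)
  if (!fmt %in% c("PDBQT", "MOL2")) {
    stop(sprintf("ligand_library_format must be PDBQT or MOL2 (got '%s')", fmt),
         call. = FALSE)
  }
  scen_names <- strsplit(get1("docking_scenario_names", required = TRUE),
                         "[,:]")[[1]]
  scen_names <- trimws(scen_names)
  if (anyDuplicated(scen_names)) {
    stop("docking scenario names must be unique", call. = FALSE)
  }
  input_files <- get1("input_files", file.path(base_dir, "input-files"))
  rel <- function(p) if (grepl("^/", p)) p else file.path(base_dir, p)
  scenarios <- lapply(scen_names, function(nm) {
    cfg <- file.path(rel(input_files), nm, "config.txt")
    if (!file.exists(cfg)) {
      stop(sprintf("scenario config not found: %s", cfg), call. = FALSE)
    }
    parse_scenario_config(path = cfg, name = nm)
  })
  names(scenarios) <- scen_names
  structure(list(
    ligand_library_format = fmt,
    scenarios = scenarios,
    workers = as.integer(get1("workers", "1")),
    seed = as.integer(get1("seed", "1")),
    library_root = rel(get1("library_root", required = TRUE)),
    output_root = rel(get1("output_root", required = TRUE)),
    receptor = if (!is.null(get1("receptor"))) rel(get1("receptor")) else NULL,
    use_local_scratch = tolower(get1("use_local_scratch", "no")) %in%
      c("yes", "true", "1")),
    class = "control_file")
}
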