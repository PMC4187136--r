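# state serialization and the configuration-driven run interface

# atomic write: render to a temp file in the target directory, then rename
pc_atomic_write <- function(path, writer) {
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".tmp")
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  writer(tmp)
  if (!file.rename(tmp, path))
    pc_stop("protocean_io_error", "cannot write '%s'", path)
  invisible(path)
}

#' Write an equilibrium state to JSON
#'
#' All numerics are serialised at full precision so that
#' `read_state(write_state(x))` is the identity to better than 1e-12
#' relative on every field; key order is stable for diff-based testing.
#'
#' @param state an `equilibrium_state`; @param path output path.
#' @return `path`, invisibly.
#' @export
write_state <- function(state, path) {
  doc <- list(
    schema = "protocean-state-v1",
    pH = state$pH,
    water_moles = state$water_moles,
    total_G = state$total_G,
    mode = state$mode,
    h2_partial_pressure = state$h2_partial_pressure,
    solid_assemblage = as.list(state$solid_assemblage),
    species_moles = as.list(state$species_moles),
    molalities = as.list(state$molalities),
    gas_partial_pressures = as.list(state$gas_partial_pressures),
    gas_moles_total = state$gas_moles_total,
    saturation_indices = as.list(state$saturation_indices),
    lambda = as.list(state$lambda),
    theta_q = state$theta_q,
    active_species = as.list(state$active_species),
    composition = list(
      element_totals = as.list(state$composition$element_totals),
      nitrogen_reduced = state$composition$nitrogen_reduced),
    max_residual = state$max_residual)
  pc_atomic_write(path, function(tmp)
    jsonlite::write_json(doc, tmp, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, null = "null"))
}

#' Read an equilibrium state written by [write_state()]
#'
#' @param path JSON path.
#' @return an `equilibrium_state`.
#' @export
read_state <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(doc$schema) || doc$schema != "protocean-state-v1")
    pc_stop("protocean_bad_schema", "not a protocean state file: '%s'", path)
  num_field <- function(key) {
    v <- unlist(doc[[key]])
    if (is.null(v)) return(setNames(numeric(0), character(0)))
    if (!is.numeric(v))
      pc_stop("protocean_bad_schema", "field '%s' must be numeric", key)
    v
  }
  sm <- num_field("species_moles")
  bad <- names(sm)[sm < 0]
  if (length(bad))
    pc_stop("protocean_bad_schema", "negative moles for species: %s",
            paste(bad, collapse = ", "))
  comp <- system_composition(unlist(doc$composition$element_totals),
                             doc$composition$nitrogen_reduced)
  structure(list(
    species_moles = sm,
    molalities = num_field("molalities"),
    solid_assemblage = unlist(doc$solid_assemblage) %||% character(0),
    pH = doc$pH,
    gas_partial_pressures = num_field("gas_partial_pressures"),
    gas_moles_total = doc$gas_moles_total,
    water_moles = doc$water_moles,
    total_G = doc$total_G,
    saturation_indices = num_field("saturation_indices"),
    lambda = num_field("lambda"),
    theta_q = doc$theta_q,
    composition = comp,
    mode = doc$mode,
    h2_partial_pressure = doc$h2_partial_pressure,
    active_species = unlist(doc$active_species),
    newton_iterations = NA_integer_,
    assemblage_iterations = NA_integer_,
    max_residual = doc$max_residual), class = "equilibrium_state")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Load a run configuration
#'
#' YAML (or JSON) file with fields `operation` (one of `validate-db`,
#' `solve`, `sweep`, `threshold`, `build-scenario`), `database` (path;
#' omit for the shipped fixture), `scenario` (named overrides of
#' [scenario_spec()] fields), and operation-specific blocks `axis1`/`axis2`
#' (sweep), `axis`/`predicate`/`bracket`/`tol` (threshold), plus `out`.
#'
#' @param path config file path.
#' @return a validated `run_config` list.
#' @export
load_run_config <- function(path) {
  if (!file.exists(path))
    pc_stop("protocean_io_error", "config '%s' does not exist", path)
  cfg <- yaml::read_yaml(path)
  ops <- c("validate-db", "solve", "sweep", "threshold", "build-scenario")
  if (is.null(cfg$operation) || !cfg$operation %in% ops)
    pc_stop("protocean_bad_config",
            "config field 'operation' must be one of: %s",
            paste(ops, collapse = ", "))
  if (!is.null(cfg$database) && !file.exists(cfg$database))
    pc_stop("protocean_bad_config", "config field 'database': file '%s' missing",
            cfg$database)
  if (cfg$operation == "sweep" && (is.null(cfg$axis1) || is.null(cfg$axis2)))
    pc_stop("protocean_bad_config", "sweep needs config fields 'axis1','axis2'")
  if (cfg$operation == "threshold" &&
      (is.null(cfg$axis) || is.null(cfg$bracket)))
    pc_stop("protocean_bad_config",
            "threshold needs config fields 'axis','bracket'")
  structure(cfg, class = "run_config")
}

# build a scenario_spec from the config's scenario block
pc_config_scenario <- function(cfg) {
  spec <- default_early_ocean()
  for (k in names(cfg$scenario)) {
    if (!k %in% names(spec))
      pc_stop("protocean_bad_config", "unknown scenario field '%s'", k)
    spec[[k]] <- cfg$scenario[[k]]
  }
  spec
}

pc_config_axis <- function(block) {
  axis_spec(block$parameter, block$lower, block$upper,
            n = block$n %||% 40L, scale = block$scale %||% "log")
}

#' Execute a run configuration
#'
#' Dispatches on the configured operation, writes the primary artifact and
#' an accompanying `<out>.manifest.json` (config echo, database version,
#' package version, residual summary) atomically, and returns the exit
#' status: 0 on success, nonzero if validation found issues or any solve
#' failed.
#'
#' @param config a `run_config` from [load_run_config()], or a path.
#' @param quiet suppress progress messages.
#' @return integer exit status, invisibly.
#' @export
pc_run <- function(config, quiet = FALSE) {
  if (is.character(config)) config <- load_run_config(config)
  db <- if (is.null(config$database)) default_thermodb()
        else load_thermodb(config$database)
  out <- config$out %||% "protocean_out"
  status <- 0L
  note <- function(...) if (!quiet) message(...)
  summary_info <- list()

  if (config$operation == "validate-db") {
    findings <- validate_thermodb(db)
    if (nrow(findings)) {
      status <- 1L
      if (!quiet) print(findings)
    }
    summary_info$findings <- nrow(findings)
    note(sprintf("validate-db: %d finding(s)", nrow(findings)))
  } else if (config$operation == "build-scenario") {
    spec <- pc_config_scenario(config)
    comp <- build_composition(spec)
    pc_atomic_write(out, function(tmp)
      jsonlite::write_json(list(element_totals =
                                  as.list(comp$element_totals),
                                nitrogen_reduced = comp$nitrogen_reduced),
                           tmp, auto_unbox = TRUE, digits = NA,
                           pretty = TRUE))
    note("build-scenario: wrote ", out)
  } else if (config$operation == "solve") {
    spec <- pc_config_scenario(config)
    st <- tryCatch(pc_solve_scenario(spec, db,
                                     calibrate = config$calibrate %||% TRUE),
                   error = function(e) e)
    if (inherits(st, "error")) {
      status <- 1L
      summary_info$error <- conditionMessage(st)
    } else {
      write_state(st, out)
      summary_info$pH <- st$pH
      summary_info$max_residual <- st$max_residual
      summary_info$assemblage <- st$solid_assemblage
      note("solve: wrote ", out)
    }
  } else if (config$operation == "sweep") {
    map <- sweep_phasemap(pc_config_scenario(config),
                          pc_config_axis(config$axis1),
                          pc_config_axis(config$axis2), db)
    export_phasemap(map, out)
    nfail <- sum(map$grid$status != "ok")
    if (nfail) status <- 1L
    summary_info$failed_cells <- nfail
    note(sprintf("sweep: wrote %s (%d failed cells)", out, nfail))
  } else if (config$operation == "threshold") {
    pred <- switch(config$predicate %||% "struvite-present",
                   "struvite-present" = struvite_present,
                   "struvite-only" = function(s) struvite_only(s, db),
                   pc_stop("protocean_bad_config",
                           "unknown predicate '%s'", config$predicate))
    th <- find_threshold(pc_config_scenario(config), config$axis, pred,
                         as.numeric(unlist(config$bracket)),
                         tol = config$tol %||% 1e-3, db = db)
    pc_atomic_write(out, function(tmp)
      jsonlite::write_json(unclass(th), tmp, auto_unbox = TRUE, digits = NA,
                           pretty = TRUE))
    summary_info$threshold <- th$threshold
    note(sprintf("threshold: %s = %.6g", config$axis, th$threshold))
  }

  manifest <- list(config = unclass(config), database_version = db$version,
                   tool_version = tryCatch(
                     as.character(utils::packageVersion("protocean")),
                     error = function(e) "dev"),
                   status = status, summary = summary_info)
  pc_atomic_write(paste0(out, ".manifest.json"), function(tmp)
    jsonlite::write_json(manifest, tmp, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE))
  invisible(status)
}
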