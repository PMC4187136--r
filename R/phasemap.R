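#' Axis specification for a parameter sweep
#'
#' @param parameter one of `mg_ca_ratio`, `ammonium_molality`,
#'   `total_phosphate`, `h2_partial_pressure`, `ammonia_fraction`.
#' @param lower,upper bounds (positive for log scale).
#' @param n number of grid points (>= 2).
#' @param scale `"log"` (default, matching the figure axes) or `"linear"`.
#' @return object of class `axis_spec`.
#' @export
axis_spec <- function(parameter, lower, upper, n = 40L,
                      scale = c("log", "linear")) {
  scale <- match.arg(scale)
  params <- c("mg_ca_ratio", "ammonium_molality", "total_phosphate",
              "h2_partial_pressure", "ammonia_fraction")
  if (!parameter %in% params)
    pc_stop("protocean_bad_axis", "unknown parameter '%s'", parameter)
  if (!(lower < upper)) pc_stop("protocean_bad_axis", "need lower < upper")
  if (scale == "log" && lower <= 0)
    pc_stop("protocean_bad_axis", "log-scale bounds must be positive")
  if (n < 2) pc_stop("protocean_bad_axis", "need at least 2 points")
  values <- if (scale == "log")
    10^seq(log10(lower), log10(upper), length.out = n)
  else seq(lower, upper, length.out = n)
  structure(list(parameter = parameter, lower = lower, upper = upper,
                 n = as.integer(n), scale = scale, values = values),
            class = "axis_spec")
}

#' Classify the phosphate-mineral assemblage of a solved state
#'
#' The label is the sorted `+`-joined set of phosphate-bearing solids with
#' more than `floor` moles (`"none"` if empty); non-phosphate solids
#' (oxides/hydroxides) are reported in the `"oxides"` attribute.
#'
#' @param state an `equilibrium_state`.
#' @param db the `thermo_db`.
#' @param floor presence floor in moles per kg water.
#' @return character label with attribute `oxides`.
#' @export
classify_assemblage <- function(state, db = default_thermodb(),
                                floor = 1e-12) {
  sol <- state$solid_assemblage
  sol <- sol[state$species_moles[sol] > floor]
  hasP <- db$formula[sol, "P"] > 0
  label <- if (any(hasP)) paste(sort(sol[hasP]), collapse = "+") else "none"
  attr(label, "oxides") <- sort(sol[!hasP])
  label
}

#' Is struvite present in the equilibrium assemblage?
#'
#' @param state an `equilibrium_state`.
#' @param floor presence floor, mol per kg water.
#' @return logical.
#' @export
struvite_present <- function(state, floor = 1e-12) {
  "Struvite" %in% state$solid_assemblage &&
    state$species_moles[["Struvite"]] > floor
}

#' Is struvite the sole phosphate-bearing solid?
#'
#' @inheritParams struvite_present
#' @param db the `thermo_db`.
#' @return logical.
#' @export
struvite_only <- function(state, db = default_thermodb(), floor = 1e-12) {
  struvite_present(state, floor) &&
    classify_assemblage(state, db, floor) == "Struvite"
}

#' Sweep two scenario parameters and map the equilibrium assemblages
#'
#' Solves one full equilibrium per grid cell (recalibrating the sulfide
#' buffer for each cell's own load, so every cell sits in the buffered pH
#' band) and records the assemblage label, struvite moles and pH. Failed
#' cells are flagged in `status`, never silently filled. The pipeline
#' contains no randomness: identical inputs give identical maps.
#'
#' @param template a `scenario_spec` providing all non-swept parameters.
#' @param axis1,axis2 two [axis_spec()]s naming distinct parameters.
#' @param db a `thermo_db`; @param opts optional [solver_options()].
#' @param target_pH buffer calibration target.
#' @return object of class `phase_map`: long-format data.frame in `$grid`
#'   plus axis and provenance metadata.
#' @export
sweep_phasemap <- function(template, axis1, axis2, db = default_thermodb(),
                           opts = NULL, target_pH = 7.8) {
  if (axis1$parameter == axis2$parameter)
    pc_stop("protocean_bad_axis", "axes must name distinct parameters")
  cells <- expand.grid(i = seq_len(axis1$n), j = seq_len(axis2$n))
  rows <- vector("list", nrow(cells))
  for (k in seq_len(nrow(cells))) {
    v1 <- axis1$values[cells$i[k]]; v2 <- axis2$values[cells$j[k]]
    spec <- pc_set_param(pc_set_param(template, axis1$parameter, v1),
                         axis2$parameter, v2)
    res <- tryCatch(pc_solve_scenario(spec, db, opts, target_pH),
                    error = function(e) e)
    if (inherits(res, "error")) {
      rows[[k]] <- data.frame(x1 = v1, x2 = v2, label = NA_character_,
                              struvite_mol = NA_real_, pH = NA_real_,
                              status = paste0("failed: ",
                                              conditionMessage(res)))
    } else {
      rows[[k]] <- data.frame(
        x1 = v1, x2 = v2, label = as.character(classify_assemblage(res, db)),
        struvite_mol = if (struvite_present(res))
          res$species_moles[["Struvite"]] else 0,
        pH = res$pH, status = "ok")
    }
  }
  grid <- do.call(rbind, rows)
  names(grid)[1:2] <- c(axis1$parameter, axis2$parameter)
  structure(list(grid = grid, axis1 = axis1, axis2 = axis2,
                 template = template, db_version = db$version,
                 target_pH = target_pH),
            class = "phase_map")
}

#' @export
print.phase_map <- function(x, ...) {
  cat(sprintf("<phase_map> %s x %s (%d x %d cells)\n", x$axis1$parameter,
              x$axis2$parameter, x$axis1$n, x$axis2$n))
  print(table(x$grid$label, useNA = "ifany"))
  invisible(x)
}

#' Locate a phase boundary by bisection
#'
#' Bisects one scenario parameter (in log space by default, matching the
#' figures' log axes) for the point where an assemblage predicate flips.
#' The predicate must differ at the two bracket ends and be monotone along
#' the axis (caller-asserted).
#'
#' @param template a `scenario_spec`.
#' @param axis parameter name (see [axis_spec()]).
#' @param predicate function of an `equilibrium_state` returning a logical,
#'   e.g. [struvite_present()].
#' @param bracket numeric `c(lo, hi)`.
#' @param tol relative bracket width at which to stop (default 1e-3).
#' @param scale `"log"` or `"linear"` bisection.
#' @param db a `thermo_db`; @param opts optional [solver_options()];
#' @param target_pH buffer calibration target.
#' @param description free-text predicate description for the result.
#' @return object of class `threshold_result` with fields `axis`,
#'   `threshold`, `bracket`, `width`, `iterations`, `predicate`.
#' @export
find_threshold <- function(template, axis, predicate, bracket, tol = 1e-3,
                           scale = "log", db = default_thermodb(),
                           opts = NULL, target_pH = 7.8,
                           description = "assemblage predicate") {
  lo <- bracket[1]; hi <- bracket[2]
  if (!(lo < hi) || (scale == "log" && lo <= 0))
    pc_stop("protocean_bad_axis", "invalid bracket [%g, %g]", lo, hi)
  eval_at <- function(v) {
    st <- pc_solve_scenario(pc_set_param(template, axis, v), db, opts,
                            target_pH)
    isTRUE(predicate(st))
  }
  p_lo <- eval_at(lo); p_hi <- eval_at(hi)
  if (p_lo == p_hi)
    pc_stop("protocean_bracket_error",
            "predicate is %s at both bracket ends", p_lo)
  it <- 0L
  while ((hi - lo) / lo > tol) {
    it <- it + 1L
    if (it > 200L) break
    mid <- if (scale == "log") sqrt(lo * hi) else (lo + hi) / 2
    if (eval_at(mid) == p_hi) hi <- mid else lo <- mid
  }
  structure(list(axis = axis,
                 threshold = if (scale == "log") sqrt(lo * hi)
                             else (lo + hi) / 2,
                 bracket = c(lo, hi), width = (hi - lo) / lo,
                 iterations = it, predicate = description),
            class = "threshold_result")
}

#' @export
print.threshold_result <- function(x, ...) {
  cat(sprintf("<threshold_result> %s = %.6g (%s)\n", x$axis, x$threshold,
              x$predicate))
  cat(sprintf("  bracket [%.6g, %.6g], rel width %.3g, %d bisections\n",
              x$bracket[1], x$bracket[2], x$width, x$iterations))
  invisible(x)
}

#' Export a phase map to CSV
#'
#' Long format, one row per cell, with `#`-prefixed metadata lines (axes,
#' template digest, database version) ahead of the header; numbers carry 17
#' significant digits so [read_phasemap()] round-trips losslessly.
#'
#' @param map a `phase_map`; @param path output file.
#' @return `path`, invisibly.
#' @export
export_phasemap <- function(map, path) {
  meta <- c(
    sprintf("# protocean phase_map | db %s | target_pH %.17g",
            map$db_version, map$target_pH),
    sprintf("# axis1 %s %s [%.17g, %.17g] n=%d", map$axis1$parameter,
            map$axis1$scale, map$axis1$lower, map$axis1$upper, map$axis1$n),
    sprintf("# axis2 %s %s [%.17g, %.17g] n=%d", map$axis2$parameter,
            map$axis2$scale, map$axis2$lower, map$axis2$upper, map$axis2$n))
  g <- map$grid
  num <- vapply(g, is.numeric, logical(1))
  g[num] <- lapply(g[num], function(col) sprintf("%.17g", col))
  con <- file(path, "w"); on.exit(close(con))
  writeLines(meta, con)
  write.csv(g, con, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Read a phase map written by [export_phasemap()]
#'
#' @param path CSV path.
#' @return a `phase_map` (grid and axis metadata; no template).
#' @export
read_phasemap <- function(path) {
  lines <- readLines(path)
  meta <- lines[startsWith(lines, "#")]
  ax <- lapply(meta[grepl("^# axis", meta)], function(ln) {
    m <- regmatches(ln, regexec(
      "^# axis[12] (\\S+) (\\S+) \\[(\\S+), (\\S+)\\] n=(\\d+)$", ln))[[1]]
    axis_spec(m[2], as.numeric(m[4]), as.numeric(m[5]),
              n = as.integer(m[6]), scale = m[3])
  })
  grid <- read.csv(text = lines[!startsWith(lines, "#")],
                   stringsAsFactors = FALSE)
  dbv <- sub("^# protocean phase_map \\| db (.*) \\| target_pH.*$", "\\1",
             meta[1])
  tph <- as.numeric(sub("^.*target_pH ", "", meta[1]))
  structure(list(grid = grid, axis1 = ax[[1]], axis2 = ax[[2]],
                 template = NULL, db_version = dbv, target_pH = tph),
            class = "phase_map")
}
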