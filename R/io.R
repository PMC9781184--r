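#' Configuration files, result export and the command-line interface
#'
#' Run configurations are JSON documents with `model`, `solver`, `contact`
#' and `output` blocks. Lengths may be given as numbers (mm) or strings with
#' units (`"0.07 m"`, `"70 mm"`); moduli and penalties are MPa, forces N.
#' Unknown keys are rejected with the offending name, so typos do not pass
#' silently.
#'
#' @name io_cli
NULL

#' Parse a length into millimetres
#'
#' @param x numeric (taken as mm) or string `"<value> <unit>"` with unit
#'   `m`, `cm` or `mm`
#' @return length in mm
#' @export
parse_length_mm <- function(x) {
  if (is.numeric(x)) return(as.numeric(x))
  s <- trimws(as.character(x))
  m <- regmatches(s, regexec("^([0-9.eE+-]+)\\s*(mm|cm|m)$", s))[[1]]
  if (length(m) != 3L)
    stop(sprintf("parse_length_mm: cannot parse length '%s' (use e.g. \"0.07 m\" or \"70 mm\")", s))
  as.numeric(m[2]) * switch(m[3], mm = 1, cm = 10, m = 1000)
}

.check_keys <- function(block, allowed, where) {
  unknown <- setdiff(names(block), allowed)
  if (length(unknown))
    stop(sprintf("load_config: unknown key(s) in '%s': %s", where,
                 paste(unknown, collapse = ", ")))
}

.require_positive <- function(x, key) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x <= 0))
    stop(sprintf("load_config: '%s' must be positive and finite", key))
  x
}

#' Load and validate a run configuration
#'
#' @param path path to a JSON configuration file
#' @return list with a validated [tendon_spec()] under `$spec`, plus
#'   `$output_dir` and `$seed`
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("load_config: no such file: %s", path))
  cfg <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  .check_keys(cfg, c("model", "solver", "contact", "output", "seed"), "<top level>")
  mdl <- if (is.null(cfg$model)) list() else cfg$model
  .check_keys(mdl, c("L", "twist_deg", "areas", "c10", "k_factor",
                     "convention", "elements", "handedness"), "model")
  sol <- if (is.null(cfg$solver)) list() else cfg$solver
  .check_keys(sol, c("loads", "tol", "max_iter", "n_cubature", "n_axial"), "solver")
  con <- if (is.null(cfg$contact)) list() else cfg$contact
  .check_keys(con, c("enabled", "pn", "mode", "n_arc", "facing_dist", "n_axial"),
              "contact")
  out <- if (is.null(cfg$output)) list() else cfg$output
  .check_keys(out, c("dir"), "output")
  args <- list()
  if (!is.null(mdl$L)) args$L <- parse_length_mm(mdl$L)
  if (!is.null(mdl$twist_deg)) args$twist_deg <- mdl$twist_deg
  if (!is.null(mdl$areas)) args$areas <- .require_positive(unlist(mdl$areas), "model.areas")
  if (!is.null(mdl$c10)) args$c10 <- .require_positive(unlist(mdl$c10), "model.c10")
  if (!is.null(mdl$k_factor)) args$k_factor <- .require_positive(mdl$k_factor, "model.k_factor")
  if (!is.null(mdl$convention)) args$convention <- mdl$convention
  if (!is.null(mdl$elements)) args$n_elements <- .require_positive(mdl$elements, "model.elements")
  if (!is.null(mdl$handedness)) args$handedness <- mdl$handedness
  if (!is.null(sol$loads)) args$loads <- .require_positive(sol$loads, "solver.loads")
  if (!is.null(sol$n_cubature)) args$n_cubature <- .require_positive(sol$n_cubature, "solver.n_cubature")
  if (!is.null(sol$n_axial)) args$n_axial <- .require_positive(sol$n_axial, "solver.n_axial")
  if (length(con)) {
    if (!is.null(con$pn)) .require_positive(con$pn, "contact.pn")
    args$contact <- con
  }
  spec <- do.call(tendon_spec, args)
  list(spec = spec,
       tol = if (is.null(sol$tol)) 1e-4 else .require_positive(sol$tol, "solver.tol"),
       max_iter = if (is.null(sol$max_iter)) 30L
                  else as.integer(.require_positive(sol$max_iter, "solver.max_iter")),
       output_dir = if (is.null(out$dir)) "." else out$dir,
       seed = if (is.null(cfg$seed)) 1L else as.integer(cfg$seed))
}

#' Serialize a configuration back to JSON
#'
#' @param config a [load_config()] result
#' @param path output path
#' @export
write_config <- function(config, path) {
  sp <- config$spec
  jsonlite::write_json(list(
    model = list(L = sp$L, twist_deg = sp$twist_deg, areas = as.list(sp$areas),
                 c10 = as.list(sp$c10), k_factor = sp$k_factor,
                 convention = sp$convention, elements = sp$n_elements,
                 handedness = sp$handedness),
    solver = list(loads = sp$loads, tol = config$tol, max_iter = config$max_iter,
                  n_cubature = sp$n_cubature, n_axial = sp$n_axial),
    contact = sp$contact,
    output = list(dir = config$output_dir),
    seed = config$seed), path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Export the model geometry as legacy-ASCII VTK polydata
#'
#' The export contains each beam's centerline polyline plus cross-section
#' boundary loops at the nodal axial stations, deformed by the supplied
#' state; sufficient for visual inspection of the deformed tendon.
#'
#' @param model an [fe_model()]
#' @param q global coordinate vector (reference by default)
#' @param path output `.vtk` path
#' @param loop_pts points per cross-section loop
#' @export
write_vtk_model <- function(model, q = model$q0, path, loop_pts = 36L) {
  pts <- NULL; lines <- list()
  for (bi in seq_along(model$beams)) {
    b <- model$beams[[bi]]
    off <- model$offsets[bi]
    # centerline: node positions
    ctr <- t(vapply(seq_len(b$n_nodes), function(nd)
      q[off + (nd - 1L) * 18L + 1:3], numeric(3)))
    i0 <- if (is.null(pts)) 0L else nrow(pts)
    pts <- rbind(pts, ctr)
    lines[[length(lines) + 1L]] <- i0 + seq_len(nrow(ctr)) - 1L
    # section loops at node stations
    curve <- .section_curve(b$section)
    uu <- seq(0, curve$total, length.out = loop_pts + 1L)[seq_len(loop_pts)]
    yz <- .curve_eval(curve, uu)[, 1:2]
    for (nd in seq_len(b$n_nodes)) {
      e <- min((nd - 1L) %/% 2L + 1L, b$n_el)
      xi <- c(-1, 0, 1)[(nd - 1L) - 2L * (e - 1L) + 1L]
      Q <- matrix(q[off + b$elements[[e]]$dofs], nrow = 3L)
      loop <- t(Q %*% shape_functions(rep(xi, loop_pts), 2 * yz[, 1] / b$geom$ly,
                                      2 * yz[, 2] / b$geom$lz, b$geom))
      i0 <- nrow(pts)
      pts <- rbind(pts, loop)
      lines[[length(lines) + 1L]] <- i0 + c(seq_len(loop_pts), 1L) - 1L
    }
  }
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0",
               "tendon model export", "ASCII", "DATASET POLYDATA",
               sprintf("POINTS %d double", nrow(pts))), con)
  writeLines(apply(pts, 1L, function(p) sprintf("%.9g %.9g %.9g", p[1], p[2], p[3])), con)
  sz <- sum(vapply(lines, length, integer(1))) + length(lines)
  writeLines(sprintf("LINES %d %d", length(lines), sz), con)
  for (ln in lines)
    writeLines(paste(c(length(ln), ln), collapse = " "), con)
  invisible(path)
}

#' Write sweep results, VTK exports and a JSON run summary
#'
#' @param sweeps named list of sweep data frames from
#'   [run_elongation_sweep()] (names become file suffixes, e.g. psi angles)
#' @param model the model of the last sweep (used for the VTK export)
#' @param dir output directory (created if missing)
#' @param mesh optional [mesh_study()] data frame
#' @param export_vtk also write reference + final deformed VTK files
#' @return invisibly, the vector of files written
#' @export
write_results <- function(sweeps, model = NULL, dir = ".", mesh = NULL,
                          export_vtk = FALSE) {
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE))
    stop(sprintf("write_results: cannot create output directory '%s'", dir))
  files <- character(0)
  if (inherits(sweeps, "data.frame")) sweeps <- list(sweep = sweeps)
  combined <- NULL
  for (nmi in names(sweeps)) {
    sw <- sweeps[[nmi]]
    f <- file.path(dir, sprintf("elongation_%s.csv", nmi))
    utils::write.csv(sw, f, row.names = FALSE)
    files <- c(files, f)
    cols <- grep("^elong_soleus", names(sw))
    piece <- sw[, c(1L, cols)]
    names(piece)[2L] <- sprintf("elong_soleus_mm_%s", nmi)
    combined <- if (is.null(combined)) piece else merge(combined, piece, by = "load_N")
  }
  if (length(sweeps) > 1L) {
    f <- file.path(dir, "elongation_summary.csv")
    utils::write.csv(combined, f, row.names = FALSE)
    files <- c(files, f)
  }
  if (!is.null(mesh)) {
    f <- file.path(dir, "mesh_study.csv")
    utils::write.csv(mesh, f, row.names = FALSE)
    files <- c(files, f)
  }
  summary <- lapply(sweeps, function(sw)
    list(loads_N = sw$load_N, elong_soleus_mm = sw[[grep("^elong_soleus", names(sw))[1]]],
         iterations = sw$iterations, residual_N = sw$residual,
         max_gap_dev_mm = sw$max_gap_dev))
  f <- file.path(dir, "run_summary.json")
  jsonlite::write_json(summary, f, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  files <- c(files, f)
  if (export_vtk && !is.null(model)) {
    f <- file.path(dir, "reference.vtk")
    write_vtk_model(model, model$q0, f)
    files <- c(files, f)
    last <- sweeps[[length(sweeps)]]
    states <- attr(last, "states")
    if (!is.null(states)) {
      f <- file.path(dir, "deformed_final.vtk")
      write_vtk_model(model, states[[length(states)]]$q, f)
      files <- c(files, f)
    }
  }
  invisible(files)
}

#' Command-line entry point
#'
#' Subcommands: `run -c config.json` (single solve at the configured twist),
#' `sweep -c config.json [--psi 0,15,45]` (load-elongation tables),
#' `mesh-study -c config.json [--elements 1,2,4]`,
#' `cubature-show -c boundary.txt [--n 2]` (rule CSV to stdout path).
#' Exit codes: 0 success, 2 configuration error, 3 solver failure.
#'
#' @param args character vector of CLI arguments (default: the command line)
#' @return integer exit status, invisibly
#' @export
tendon_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  opt <- function(flag, default = NULL) {
    i <- which(args == flag)
    if (length(i)) args[i[1] + 1L] else default
  }
  usage <- function() {
    message("usage: tendon <run|sweep|mesh-study|cubature-show> -c <file> [options]")
    2L
  }
  if (!length(args)) return(invisible(usage()))
  cmd <- args[1L]
  status <- tryCatch({
    if (cmd == "cubature-show") {
      spec <- read_boundary(opt("-c", stop("cubature-show: missing -c <boundary file>")))
      rule <- build_cubature(spec, as.integer(opt("--n", "2")))
      out <- opt("--out", "cubature.csv")
      write_cubature_csv(rule, out)
      message(sprintf("wrote %s (%d nodes, area %.6g mm^2)", out,
                      length(rule$weights), rule$area))
      return(invisible(0L))
    }
    cfgp <- opt("-c", NULL)
    if (is.null(cfgp)) return(invisible(usage()))
    cfg <- load_config(cfgp)
    dir <- opt("--out", cfg$output_dir)
    solve_one <- function(sp) {
      m <- build_tendon_model(sp)
      sw <- tryCatch(run_elongation_sweep(m, tol = cfg$tol, max_iter = cfg$max_iter),
                     error = function(e)
                       stop(structure(class = c("ancf_solver_failure", "error", "condition"),
                                      list(message = conditionMessage(e), call = NULL))))
      list(model = m, sweep = sw)
    }
    if (cmd == "run") {
      r <- solve_one(cfg$spec)
      write_results(list(run = r$sweep), r$model, dir, export_vtk = TRUE)
      print(r$sweep[, 1:4])
    } else if (cmd == "sweep") {
      psis <- as.numeric(strsplit(opt("--psi", "0,15,45"), ",")[[1]])
      sweeps <- list(); mlast <- NULL
      for (p in psis) {
        sp <- cfg$spec; sp$twist_deg <- p
        r <- solve_one(sp)
        sweeps[[sprintf("psi%g", p)]] <- r$sweep
        mlast <- r$model
      }
      write_results(sweeps, mlast, dir, export_vtk = TRUE)
    } else if (cmd == "mesh-study") {
      els <- as.integer(strsplit(opt("--elements", "1,2,4"), ",")[[1]])
      ms <- mesh_study(cfg$spec, els, tol = cfg$tol)
      write_results(list(), NULL, dir, mesh = ms)
      print(ms)
    } else {
      return(invisible(usage()))
    }
    0L
  },
  ancf_solver_failure = function(e) { message("solver failure: ", conditionMessage(e)); 3L },
  error = function(e) { message("configuration error: ", conditionMessage(e)); 2L })
  invisible(status)
}
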