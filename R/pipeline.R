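# End-to-end pipeline: homogenize -> fit surrogate -> optimize -> build and
# export the graded lattice, with all artifacts and the resolved
# configuration written to a run directory.

#' Pipeline configuration
#'
#' Collects the sub-configurations of the full design workflow. Defaults
#' follow the titanium cage design study: solid titanium (Es = 110000 MPa,
#' nus = 0.3), octet cells, densities 0.1-0.8 for the sweep, GA bounds
#' [0.2, 0.7] with volume constraint 0.4.
#'
#' @param cell_type unit cell type.
#' @param cell_edge cell edge length (mm).
#' @param resolution homogenization voxel resolution per cell edge.
#' @param sweep_rho densities of the homogenization sweep.
#' @param Es,nus solid Young's modulus (MPa) and Poisson ratio.
#' @param liner,cement auxiliary material constants `(E MPa, nu)` kept for
#'   assembly models.
#' @param ga a [ga_config()].
#' @param geometry benchmark geometry: `"cantilever"` or `"cage"`.
#' @param geometry_args arguments for the fixture generator.
#' @param seed seed for all randomness in the run.
#' @param out_dir run directory.
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(cell_type = "octet", cell_edge = 1.35,
                            resolution = 48, sweep_rho = seq(0.1, 0.8, 0.1),
                            Es = 110000, nus = 0.3,
                            liner = c(E = 1000, nu = 0.4),
                            cement = c(E = 2500, nu = 0.3),
                            ga = ga_config(), geometry = c("cantilever", "cage"),
                            geometry_args = list(), seed = 1L,
                            out_dir = tempfile("fglattice_run")) {
  geometry <- match.arg(geometry)
  stopifnot(Es > 0, nus > 0, nus < 0.5, resolution >= 8,
            all(sweep_rho > 0), all(sweep_rho < 1))
  if (!inherits(ga, "ga_config")) stop("`ga` must be a ga_config()", call. = FALSE)
  # validate bounds against the sweep domain before any compute
  if (ga$rho_bounds[1] < min(sweep_rho) - 1e-9 ||
      ga$rho_bounds[2] > max(sweep_rho) + 1e-9) {
    stop("GA rho_bounds outside the surrogate fitting domain", call. = FALSE)
  }
  ga$seed <- as.integer(seed)
  structure(list(cell_type = cell_type, cell_edge = cell_edge,
                 resolution = as.integer(resolution), sweep_rho = sweep_rho,
                 Es = Es, nus = nus, liner = liner, cement = cement,
                 ga = ga, geometry = geometry, geometry_args = geometry_args,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "pipeline_config")
}

#' Run the full graded-lattice design pipeline
#'
#' Stages: (1) homogenization density sweep of the unit cell; (2) polynomial
#' surrogate fit; (3) GA compliance minimization on the benchmark geometry;
#' (4) graded-lattice construction and STL export. Artifacts written to the
#' run directory: `sweep.csv`, `surrogate.json`, `history.csv`,
#' `density.vtk`, `lattice.stl`, `summary.json`, and the resolved
#' `config.json`.
#'
#' @param config a [pipeline_config()].
#' @param verbose print stage progress.
#' @return (invisibly) a list with the sweep, surrogate, design, lattice
#'   model, and the summary list.
#' @export
run_pipeline <- function(config = pipeline_config(), verbose = TRUE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (verbose) message(sprintf(...))
  jsonlite::write_json(
    lapply(unclass(config), function(x) if (inherits(x, "ga_config")) unclass(x) else x),
    file.path(config$out_dir, "config.json"), auto_unbox = TRUE, digits = NA,
    force = TRUE)

  stage <- "homogenization sweep"
  out <- tryCatch({
    say("[1/4] homogenization sweep (%s, n = %d)", config$cell_type,
        config$resolution)
    sweep <- density_sweep(config$cell_type, config$sweep_rho,
                           Es = config$Es, nus = config$nus,
                           n = config$resolution, l = config$cell_edge)
    write_sweep_csv(sweep, file.path(config$out_dir, "sweep.csv"))

    stage <- "surrogate fit"
    say("[2/4] surrogate fit")
    surr <- fit_surrogate(sweep)
    write_surrogate_json(surr, file.path(config$out_dir, "surrogate.json"))
    say("      R^2(E) = %.5f, R^2(nu) = %.5f", surr$r2_E, surr$r2_nu)

    stage <- "GA optimization"
    say("[3/4] GA compliance minimization (%s fixture)", config$geometry)
    bench <- if (config$geometry == "cantilever") {
      list(mesh = do.call(make_cantilever, config$geometry_args))
    } else {
      do.call(make_cage_benchmark, config$geometry_args)
    }
    mesh <- bench$mesh
    design <- optimize_lattice_density(mesh, surr, config$ga)
    write_history_csv(design, file.path(config$out_dir, "history.csv"))
    sol <- fe_solve(mesh, stiff = assemble(mesh, densities = design$rho,
                                           surrogate = surr))
    write_vtk_grid(mesh, file.path(config$out_dir, "density.vtk"),
                   cell_data = list(rho = design$rho, von_mises = sol$vm,
                                    energy = sol$element_energy))

    stage <- "lattice build"
    say("[4/4] graded lattice build + STL export")
    lat <- build_lattice(mesh, design$rho, cell_type = config$cell_type)
    export_stl(lat, file.path(config$out_dir, "lattice.stl"))
    export_wireframe(lat, file.path(config$out_dir, "lattice_nodes.csv"),
                     file.path(config$out_dir, "lattice_struts.csv"))

    summary <- list(final_compliance = design$compliance,
                    volume_fraction = mean(design$rho),
                    rho_min = min(design$rho), rho_max = max(design$rho),
                    peak_von_mises = max(sol$vm),
                    converged_at = design$converged_at,
                    generations = nrow(design$history),
                    r2_E = surr$r2_E, r2_nu = surr$r2_nu,
                    seed = config$seed)
    jsonlite::write_json(summary, file.path(config$out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA)
    list(sweep = sweep, surrogate = surr, design = design, lattice = lat,
         solution = sol, summary = summary, dir = config$out_dir)
  }, error = function(e) {
    stop(sprintf("pipeline failed at stage '%s': %s (partial artifacts kept in %s)",
                 stage, conditionMessage(e), config$out_dir), call. = FALSE)
  })
  invisible(out)
}
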