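# Config-driven orchestration: validate a run configuration, execute the
# requested stages (prep -> structure -> binding -> tdfs) on the trimmed
# analysis window, and collect everything into a reproducible report.

#' Build and validate a run configuration
#'
#' Either programmatic (a named list) or loaded from YAML. Recognised fields:
#' `trajectory` (GRO/XYZ path) or `synthetic` (arguments to
#' [membrane_spec()]), `group_map` (YAML path; default map if absent),
#' `window` (`start`/`end`, ns), `lipids_per_leaflet`, `bin_width`,
#' `n_blocks`, `contact_cutoff`, `cutoffs` (named, nm), `seed`, `tdfs`
#' (decay/IRF/steady-state paths or a `synthetic` block), `prep` (arguments
#' to [composition()]), `output_dir`.
#'
#' @param config named list or YAML file path
#' @return validated config, class `run_config`
#' @export
run_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  defaults <- list(bin_width = 0.1, n_blocks = 5, contact_cutoff = 0.42,
                   cutoffs = list(phosphate = 0.33, carbonyl = 0.33,
                                  carboxylate = 0.33),
                   hydration_cutoffs = list(carbonyl = 0.24, phosphate = 0.335),
                   seed = 1)
  for (nm in names(defaults))
    if (is.null(config[[nm]])) config[[nm]] <- defaults[[nm]]
  for (p in c("trajectory", "group_map")) {
    if (!is.null(config[[p]]) && !file.exists(config[[p]]))
      stop(sprintf("config path '%s' does not exist: %s", p, config[[p]]))
  }
  structure(config, class = c("run_config", "list"))
}

#' Run the configured analysis pipeline
#'
#' Stages run in order on the analysis window; a stage failure is recorded in
#' the report (with `status = "error"`) and later dependent stages are
#' skipped. Identical config + seed give identical reports.
#'
#' @param config a [run_config()] (or anything it accepts)
#' @return object of class `run_report`: per-stage results, warnings, and
#'   provenance (config hash, seed, package version)
#' @export
run_pipeline <- function(config) {
  config <- run_config(config)
  report <- list(stages = list(), warnings = character(),
                 provenance = list(
                   config_hash = object_hash(unclass(config)),
                   seed = config$seed,
                   package_version = as.character(utils::packageVersion("lipidion"))))
  note <- function(w) report$warnings <<- c(report$warnings, w)
  run_stage <- function(name, fun) {
    res <- withCallingHandlers(
      tryCatch(fun(), error = function(e)
        structure(list(message = conditionMessage(e)), class = "stage_error")),
      warning = function(w) { note(conditionMessage(w)); invokeRestart("muffleWarning") })
    report$stages[[name]] <<- if (inherits(res, "stage_error"))
      list(status = "error", error = res$message)
    else c(list(status = "ok"), res)
    !inherits(res, "stage_error")
  }

  if (!is.null(config$prep))
    run_stage("prep", function() {
      comp <- do.call(composition, config$prep)
      list(composition = unclass(comp))
    })

  traj <- NULL
  truth <- NULL
  if (!is.null(config$synthetic)) {
    ok <- run_stage("simulate", function() {
      spec <- do.call(membrane_spec, config$synthetic)
      gen <- generate_membrane(spec, seed = config$seed)
      traj <<- gen$trajectory
      truth <<- gen$truth
      list(n_frames = n_frames(gen$trajectory),
           n_atoms = n_atoms(gen$trajectory))
    })
    if (!ok) return(finish_report(report, config))
  } else if (!is.null(config$trajectory)) {
    ok <- run_stage("load", function() {
      map <- if (!is.null(config$group_map)) read_group_map(config$group_map)
             else default_group_map()
      traj <<- if (grepl("\\.xyz$", config$trajectory))
        read_xyz(config$trajectory) else read_gro(config$trajectory)
      traj$topology <<- apply_group_map(traj$topology, map)
      list(n_frames = n_frames(traj), n_atoms = n_atoms(traj))
    })
    if (!ok) return(finish_report(report, config))
  }

  if (!is.null(traj) && !is.null(config$window)) {
    w <- config$window
    if (!is.null(w$start) && w$start > max(traj$time) ||
        !is.null(w$end) && w$end < min(traj$time))
      stop("analysis window lies outside the trajectory time span")
    traj <- trim_trajectory(traj, w$start, w$end)
  }

  if (!is.null(traj)) {
    lpl <- config$lipids_per_leaflet %||%
      (sum(traj$topology$group == "PHOS_P") / 2)
    run_stage("structure", function() {
      apl <- area_per_lipid(traj, lpl)
      nb <- min(config$n_blocks, n_frames(traj))
      blk <- if (nb >= 2) block_average(apl, nb) else
        list(mean = mean(apl$value), se = NA_real_)
      prof_p <- density_profile(traj, select_atoms(traj$topology, "PHOS_P"),
                                config$bin_width, symmetrize = FALSE)
      thick <- tryCatch(bilayer_thickness(prof_p), error = function(e) NA_real_)
      ang <- tryCatch(pn_angle_distribution(traj), error = function(e) NULL)
      list(apl_mean = blk$mean, apl_se = blk$se,
           thickness = as.numeric(thick),
           mean_pn_angle = if (!is.null(ang)) attr(ang, "mean_angle") else NA_real_,
           phosphate_profile = prof_p)
    })
    ions <- select_atoms(traj$topology, "CA")
    if (length(ions) > 0)
      run_stage("binding", function() {
        top <- traj$topology
        cuts <- config$cutoffs
        lp <- lipids_per_adsorbed_ion(traj, ions,
                                      contact_cutoff = config$contact_cutoff)
        sets <- list(
          phosphate = group_instances(top, "PHOS_P"),
          carbonyl = group_instances(top, c("CARBONYL_O_SN1", "CARBONYL_O_SN2")),
          carboxylate = group_instances(top, "COO_PS"))
        sets <- Filter(function(s) length(s) > 0, sets)
        coord <- coordination_of_adsorbed(
          traj, ions, sets, unlist(cuts)[names(sets)],
          contact_cutoff = config$contact_cutoff)
        n1 <- vapply(names(sets), function(nm)
          as.numeric(coordination_per_group(traj, sets[[nm]], ions,
                                            unlist(cuts)[[nm]])), numeric(1))
        hyd <- tryCatch(
          hydration_numbers(traj, unlist(config$hydration_cutoffs)),
          error = function(e) NULL)
        list(lipids_per_ion = as.numeric(lp),
             mean_adsorbed = attr(lp, "mean_adsorbed"),
             coordination_of_adsorbed = as.list(coordination_of_adsorbed_named(coord)),
             coordination_sd = as.list(attr(coord, "sd")),
             n1 = as.list(n1), hydration = hyd,
             cutoffs = cuts, contact_cutoff = config$contact_cutoff)
      })
    if (!is.null(truth)) report$ground_truth <- truth
  }

  if (!is.null(config$tdfs))
    run_stage("tdfs", function() {
      td <- config$tdfs
      if (!is.null(td$synthetic)) {
        args <- td$synthetic
        args$seed <- args$seed %||% config$seed
        dat <- do.call(generate_synthetic_tdfs, args)
      } else {
        dat <- list(
          decays = lapply(td$decays, function(p) {
            x <- utils::read.table(p, col.names = c("time", "counts"))
            decay_curve(x$time, x$counts,
                        as.numeric(sub(".*?([0-9]+)nm.*", "\\1", basename(p))))
          }),
          irf = utils::read.table(td$irf, col.names = c("time", "counts")),
          steady_state = utils::read.table(
            td$steady_state, col.names = c("wavelength", "intensity")))
      }
      res <- tdfs_analyze(dat$decays, dat$irf, dat$steady_state,
                          nu0 = td$probe %||% "laurdan",
                          n_components = td$n_components %||% "auto")
      list(delta_nu = res$delta_nu, nu_inf = res$nu_inf, tau = res$tau,
           truth = dat$truth[c("delta_nu", "tau")])
    })

  finish_report(report, config)
}

coordination_of_adsorbed_named <- function(coord) {
  stats::setNames(as.numeric(coord), names(coord))
}

finish_report <- function(report, config) {
  report$config <- unclass(config)
  report$ok <- !any(vapply(report$stages, function(s)
    identical(s$status, "error"), logical(1)))
  class(report) <- "run_report"
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("run report (%s): stages %s\n",
              if (x$ok) "ok" else "with errors",
              paste(sprintf("%s[%s]", names(x$stages),
                            vapply(x$stages, `[[`, character(1), "status")),
                    collapse = " ")))
  if (length(x$warnings) > 0)
    cat("  warnings:", length(x$warnings), "\n")
  cat("  config hash:", x$provenance$config_hash,
      " seed:", x$provenance$seed, "\n")
  invisible(x)
}

#' Write a run report to JSON (and tables to CSV)
#'
#' @param report a [run_pipeline()] report
#' @param dir output directory (created if needed)
#' @return `dir`, invisibly
#' @export
write_run_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  slim <- report
  slim$ground_truth <- NULL
  slim$stages <- lapply(slim$stages, function(s) {
    s$phosphate_profile <- NULL
    s
  })
  jsonlite::write_json(slim, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, na = "null",
                       force = TRUE)
  prof <- report$stages$structure$phosphate_profile
  if (!is.null(prof))
    utils::write.csv(as.data.frame(prof),
                     file.path(dir, "phosphate_profile.csv"), row.names = FALSE)
  invisible(dir)
}

#' Coordination/hydration summary table
#'
#' One row per (bilayer, concentration) condition: lipids per adsorbed ion,
#' per-adsorbed-ion coordination numbers for phosphate / carbonyl /
#' carboxylate, and hydration numbers for phosphate and carbonyl, each with
#' its uncertainty. Conditions without PS lipids render the carboxylate
#' column as an em-dash.
#'
#' @param reports a single [run_pipeline()] report or a list of them
#' @param labels optional data frame with columns `bilayer` and
#'   `concentration`, one row per report
#' @return data frame of class `binding_table`
#' @export
make_table1 <- function(reports, labels = NULL) {
  if (inherits(reports, "run_report")) reports <- list(reports)
  if (length(reports) == 0) stop("no reports supplied")
  rows <- lapply(seq_along(reports), function(i) {
    rp <- reports[[i]]
    b <- rp$stages$binding
    if (is.null(b) || identical(b$status, "error"))
      stop("binding stage missing or failed in report ", i)
    fmt <- function(v, s) if (is.null(v) || is.na(v)) "—" else
      sprintf("%.1f ± %.1f", v, s %||% NA_real_)
    hyd <- b$hydration
    hrow <- function(g) {
      if (is.null(hyd)) return(c(NA_real_, NA_real_))
      r <- hyd[hyd$group == g, ]
      if (nrow(r) == 0) c(NA_real_, NA_real_) else c(r$mean, r$sd)
    }
    hp <- hrow("phosphate"); hc <- hrow("carbonyl")
    data.frame(
      bilayer = labels$bilayer[i] %||% sprintf("system%d", i),
      concentration = labels$concentration[i] %||% NA,
      lipids_per_ca = b$lipids_per_ion,
      n_po4 = b$coordination_of_adsorbed$phosphate %||% NA_real_,
      n_po4_sd = b$coordination_sd$phosphate %||% NA_real_,
      n_co = b$coordination_of_adsorbed$carbonyl %||% NA_real_,
      n_co_sd = b$coordination_sd$carbonyl %||% NA_real_,
      n_coo = fmt(b$coordination_of_adsorbed$carboxylate,
                  b$coordination_sd$carboxylate),
      hyd_po4 = hp[1], hyd_po4_sd = hp[2],
      hyd_co = hc[1], hyd_co_sd = hc[2],
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("binding_table", "data.frame")
  out
}
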