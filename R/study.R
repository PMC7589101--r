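# End-to-end study driver: from a configuration describing molecules
# (trajectories per method, torsion definitions, saturation schemes,
# experimental NOE tables) to NOE comparisons, RMSD matrices, aggregate
# rows and ranking tables for every metric x point-scheme combination.
# The driver only sequences the module functions; calling them directly in
# the same order gives numerically identical results.

#' Read a study configuration from YAML
#'
#' Layout: a top-level \code{molecules} list (each entry: \code{name},
#' \code{trajectories} mapping method label to file path, \code{atoms}
#' optional atom-table override path, \code{saturation} list of
#' \code{saturated}/\code{observed} proton names, \code{experimental_noe}
#' path, optional \code{torsions} mapping label to 4 atom names) and an
#' optional \code{options} block (\code{bin_width}, \code{temperature},
#' \code{stride}, \code{k_range}, \code{seed}). Relative paths are resolved
#' against the YAML file's directory.
#'
#' @param path YAML file path.
#' @return A \code{"study_config"} list.
#' @export
read_study_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  resolve <- function(p) {
    ifelse(grepl("^(/|[A-Za-z]:)", p), p, file.path(base, p))
  }
  for (i in seq_along(cfg$molecules)) {
    mol <- cfg$molecules[[i]]
    mol$trajectories <- lapply(mol$trajectories, resolve)
    if (!is.null(mol$experimental_noe)) {
      mol$experimental_noe <- resolve(mol$experimental_noe)
    }
    if (!is.null(mol$atoms)) mol$atoms <- resolve(mol$atoms)
    cfg$molecules[[i]] <- mol
  }
  structure(validate_study_config(cfg), class = "study_config")
}

validate_study_config <- function(cfg) {
  if (!length(cfg$molecules)) stop("config has no molecules")
  labs <- unique(unlist(lapply(cfg$molecules,
                               function(m) names(m$trajectories))))
  if (!length(labs)) stop("config names no methods")
  for (mol in cfg$molecules) {
    if (is.null(mol$name)) stop("every molecule needs a name")
    for (meth in names(mol$trajectories)) {
      p <- mol$trajectories[[meth]]
      if (!file.exists(p)) {
        stop("molecule '", mol$name, "', method '", meth,
             "': trajectory file not found: ", p)
      }
    }
    if (is.null(mol$experimental_noe) || !file.exists(mol$experimental_noe)) {
      stop("molecule '", mol$name, "': experimental NOE file not found: ",
           mol$experimental_noe)
    }
  }
  opts <- cfg$options
  defaults <- list(bin_width = 5, temperature = 300, stride = 1,
                   k_range = 25:50, seed = 1L, tie_policy = "shared-mean")
  for (k in names(defaults)) if (is.null(opts[[k]])) opts[[k]] <- defaults[[k]]
  cfg$options <- opts
  cfg$methods <- labs
  cfg
}

load_molecule_inputs <- function(mol) {
  meta <- if (!is.null(mol$atoms)) read_atom_table(mol$atoms) else NULL
  exp_tab <- read_noe_table(mol$experimental_noe)
  list(metadata = meta, experimental = exp_tab)
}

#' Run a full comparison study
#'
#' For every molecule and method: read the trajectory, optionally
#' subsample, predict the ensemble NOE table for the configured saturation
#' schemes, normalize, and score against the normalized experimental
#' table. Assembles molecules x methods RMSD matrices (absolute and
#' relative, all-NOE and transglycosidic subsets where available), the
#' per-method aggregate means, rankings under both point schemes for both
#' metrics, and per-molecule torsion maps when torsions are configured.
#' Deterministic given the config.
#'
#' @param config a \code{"study_config"} (see
#'   \code{\link{read_study_config}}) or an equivalent list.
#' @param out_dir optional directory; when given, all tables are written
#'   there as delimited text together with a JSON run manifest.
#' @return A \code{"study_report"} list: \code{comparisons} (nested
#'   molecule -> method -> \code{noe_comparison}), \code{rmsd_abs},
#'   \code{rmsd_rel} (matrices), \code{aggregate} (per-method means),
#'   \code{rankings} (list over abs/rel x quadratic/linear of
#'   \code{\link{rank_methods}} results), \code{maps} (per-molecule
#'   conformation maps or NULL).
#' @export
run_study <- function(config, out_dir = NULL) {
  cfg <- if (inherits(config, "study_config")) config
         else validate_study_config(config)
  opts <- cfg$options
  mols <- vapply(cfg$molecules, `[[`, "", "name")
  methods <- cfg$methods
  rmsd_a <- matrix(NA_real_, length(mols), length(methods),
                   dimnames = list(mols, methods))
  rmsd_r <- rmsd_a
  comparisons <- list()
  maps <- list()
  for (mol in cfg$molecules) {
    inputs <- load_molecule_inputs(mol)
    comparisons[[mol$name]] <- list()
    for (meth in names(mol$trajectories)) {
      step <- paste0("molecule '", mol$name, "', method '", meth, "'")
      res <- tryCatch({
        ens <- read_ensemble(mol$trajectories[[meth]],
                             metadata = inputs$metadata)
        if (opts$stride > 1) ens <- subsample(ens, opts$stride)
        schemes <- lapply(mol$saturation, function(s) {
          saturation_scheme(s$saturated, unlist(s$observed), ens$atoms)
        })
        sim <- normalize_noe(ensemble_noe(ens, schemes))
        exp_tab <- normalize_noe(read_noe_table(mol$experimental_noe,
                                                atoms = ens$atoms))
        cmp <- compare_noe(sim, exp_tab, molecule = mol$name)
        if (!is.null(mol$torsions) && is.null(maps[[mol$name]])) {
          defs <- lapply(names(mol$torsions), function(lab) {
            torsion_definition(lab, unlist(mol$torsions[[lab]]), ens$atoms)
          })
          ts <- torsion_series(ens, defs)
          ax <- vapply(defs, `[[`, "", "label")
          maps[[mol$name]] <- conformation_map(
            ts, ax[seq_len(min(2, length(ax)))],
            bin_width = opts$bin_width, temperature = opts$temperature)
        }
        cmp
      }, error = function(e) {
        stop(step, ": ", conditionMessage(e), call. = FALSE)
      })
      comparisons[[mol$name]][[meth]] <- res
      rmsd_a[mol$name, meth] <- res$rmsd_abs
      rmsd_r[mol$name, meth] <- res$rmsd_rel
    }
  }
  rankings <- list()
  for (metric in c("abs", "rel")) {
    m <- if (metric == "abs") rmsd_a else rmsd_r
    for (scheme in c("quadratic", "linear")) {
      rankings[[paste(metric, scheme, sep = "_")]] <-
        rank_methods(m, scheme)
    }
  }
  report <- structure(list(
    comparisons = comparisons, rmsd_abs = rmsd_a, rmsd_rel = rmsd_r,
    aggregate = aggregate_table(rmsd_a), rankings = rankings,
    maps = if (length(maps)) maps else NULL, options = opts
  ), class = "study_report")
  if (!is.null(out_dir)) write_study_report(report, out_dir, cfg)
  report
}

write_study_report <- function(report, out_dir, cfg) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(x, f) {
    utils::write.table(data.frame(molecule = rownames(x), x,
                                  check.names = FALSE),
                       file.path(out_dir, f), sep = "\t", row.names = FALSE,
                       quote = FALSE)
  }
  wt(report$rmsd_abs, "rmsd_abs.tsv")
  wt(report$rmsd_rel, "rmsd_rel.tsv")
  for (nm in names(report$rankings)) {
    r <- report$rankings[[nm]]
    utils::write.table(
      data.frame(method = names(r$total_points),
                 total_points = r$total_points,
                 overall_rank = r$overall_rank),
      file.path(out_dir, paste0("ranking_", nm, ".tsv")),
      sep = "\t", row.names = FALSE, quote = FALSE)
  }
  for (nm in names(report$maps)) {
    write_conformation_map(report$maps[[nm]],
                           file.path(out_dir, paste0("map_", nm, ".tsv")))
  }
  writeLines(render_benchmark_table(report$rmsd_abs, report$rmsd_rel),
             file.path(out_dir, "summary_table.tsv"))
  manifest <- list(
    generated = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    package_version = as.character(utils::packageVersion("glynoe")),
    options = cfg$options,
    molecules = vapply(cfg$molecules, `[[`, "", "name"),
    methods = cfg$methods
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(out_dir)
}

#' Render a benchmark-style summary table
#'
#' Per-molecule absolute RMSD as a molecules x methods block, an
#' "average (all NOEs)" row (relative-RMSD averages in parentheses when
#' supplied), an optional "average (transglycosidic NOEs)" row and an
#' overall-rank row from the quadratic ranking of the absolute RMSDs.
#' Values are rendered at 2 decimals; all underlying computation keeps
#' full precision.
#'
#' @param rmsd_abs molecules x methods matrix of absolute RMSDs.
#' @param rmsd_rel optional matching matrix of relative RMSDs.
#' @param rmsd_abs_transglycosidic optional matching matrix restricted to
#'   transglycosidic pairs.
#' @return Character vector of tab-separated lines.
#' @export
render_benchmark_table <- function(rmsd_abs, rmsd_rel = NULL,
                          rmsd_abs_transglycosidic = NULL) {
  m <- as.matrix(rmsd_abs)
  fmt <- function(x) sprintf("%.2f", x)
  lines <- c(paste(c("molecule", colnames(m)), collapse = "\t"))
  for (i in seq_len(nrow(m))) {
    lines <- c(lines, paste(c(rownames(m)[i], fmt(m[i, ])), collapse = "\t"))
  }
  avg <- aggregate_table(m)$means
  avg_cells <- if (!is.null(rmsd_rel)) {
    ravg <- aggregate_table(as.matrix(rmsd_rel))$means
    sprintf("%s(%s)", fmt(avg), fmt(ravg))
  } else fmt(avg)
  lines <- c(lines, paste(c("average (all NOEs)", avg_cells),
                          collapse = "\t"))
  if (!is.null(rmsd_abs_transglycosidic)) {
    tavg <- aggregate_table(as.matrix(rmsd_abs_transglycosidic))$means
    lines <- c(lines, paste(c("average (transglycosidic NOEs)", fmt(tavg)),
                            collapse = "\t"))
  }
  if (ncol(m) >= 2) {
    rk <- rank_methods(m, "quadratic")
    rank_cells <- as.character(rk$overall_rank)
    if (rk$tied) {
      shared <- names(rk$total_points)[rk$total_points %in%
        rk$total_points[duplicated(rk$total_points)]]
      rank_cells[colnames(m) %in% shared] <-
        paste0(rank_cells[colnames(m) %in% shared], "*")
      lines <- c(lines, paste(c("overall rank", rank_cells), collapse = "\t"),
                 "* tie in total points, broken by mean RMSD")
    } else {
      lines <- c(lines, paste(c("overall rank", rank_cells), collapse = "\t"))
    }
  }
  lines
}
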