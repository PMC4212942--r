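# End-to-end pipeline: structures -> pockets -> probe fields ->
# representative points -> fingerprints -> similarity matrices -> PCA map,
# with optional projection of extra structures into the fitted map. All
# artifacts go to a plain directory with a checksummed manifest; a rerun
# with identical inputs and configuration is bit-identical.

#' Characterize one active site
#'
#' Runs the per-structure half of the pipeline: pocket detection (unless a
#' pocket is supplied), the four probe fields, representative-point
#' selection, pseudo-fields and the quadruplet fingerprint.
#'
#' @param s A `biogps_structure`.
#' @param pocket Optional `biogps_pocket`; default automatic detection.
#' @param params Probe parameters ([probe_params()]).
#' @param fp_params Fingerprint parameters ([fingerprint_params()]).
#' @param k_per_probe Representative points kept per probe (default 8;
#'   with four probes the pooled set stays around 30 points, keeping the
#'   quadruplet count in the tens of thousands).
#' @param min_sep,energy_cut Passed to [select_points()].
#' @param weight_mode Pseudo-field weighting, see [to_pseudo_field()].
#' @param probes Probe subset (default all four).
#' @param pocket_args List of extra arguments for [detect_pocket()].
#' @return A `biogps_site`: list with `id`, `structure`, `pocket`,
#'   `fields`, `points`, `pseudo_fields`, `fingerprint`.
#' @export
characterize_site <- function(s, pocket = NULL, params = probe_params(),
                              fp_params = fingerprint_params(),
                              k_per_probe = 8L, min_sep = 1.5,
                              energy_cut = -0.5,
                              weight_mode = c("binary", "energy"),
                              probes = PROBE_TYPES, pocket_args = list()) {
  weight_mode <- match.arg(weight_mode)
  stopifnot(inherits(s, "biogps_structure"))
  if (is.null(pocket))
    pocket <- do.call(detect_pocket, c(list(s), pocket_args))
  fields <- points <- pfs <- stats::setNames(vector("list", length(probes)),
                                             probes)
  for (pr in probes) {
    fields[[pr]] <- compute_field(s, pocket, pr, params)
    points[[pr]] <- select_points(fields[[pr]], k_max = k_per_probe,
                                  min_sep = min_sep,
                                  energy_cut = energy_cut)
    pfs[[pr]] <- to_pseudo_field(fields[[pr]], s, params, weight_mode)
  }
  fp <- suppressWarnings(build_fingerprint(points, s$id, fp_params))
  structure(list(id = s$id, structure = s, pocket = pocket, fields = fields,
                 points = points, pseudo_fields = pfs, fingerprint = fp),
            class = "biogps_site")
}

#' @export
print.biogps_site <- function(x, ...) {
  np <- vapply(x$points, nrow, integer(1))
  cat(sprintf("<biogps_site> %s: pocket %d nodes; points %s; %d quadruplets\n",
              x$id, length(x$pocket$idx),
              paste(names(np), np, sep = "=", collapse = " "),
              nrow(x$fingerprint$quads)))
  invisible(x)
}

#' Pipeline configuration
#'
#' Validates every setting against the preconditions of the stage it feeds
#' before any computation starts.
#'
#' @param inputs Character vector of PDB paths (>= 2, or >= 1 when
#'   projecting onto an existing model), or a list of `biogps_structure`.
#' @param out_dir Output directory.
#' @param spacing,margin Lattice settings ([grid_spec()]).
#' @param k_per_probe,min_sep,energy_cut Point selection.
#' @param weight_mode Pseudo-field weighting ([to_pseudo_field()]).
#' @param m_max,max_poses Comparison budgets.
#' @param global_mode Global-score pooling ([score_pose()]).
#' @param which Matrix driving the PCA map.
#' @param n_components Components in the map.
#' @param probes Probe subset.
#' @param seed Seed recorded in the manifest (the pipeline itself is
#'   deterministic; the seed feeds any fixture generation done upstream).
#' @param project_inputs Optional PDB paths (or structures) to project into
#'   the fitted map.
#' @param model Optional existing `biogps_upca` (or path to its JSON); when
#'   given, no model is fitted and inputs are projected onto it.
#' @param reference_sites Reference `biogps_site` list for projection onto
#'   an existing model.
#' @param params,fp_params Probe/fingerprint parameter objects.
#' @param write_intermediates Write pocket/field DX grids and fingerprint
#'   JSON per structure (default `TRUE`).
#' @return A validated `biogps_config`.
#' @export
biogps_config <- function(inputs, out_dir, spacing = 1.0, margin = 4.0,
                          k_per_probe = 8L, min_sep = 1.5,
                          energy_cut = -0.5,
                          weight_mode = c("binary", "energy"),
                          m_max = 500L, max_poses = 15L,
                          global_mode = c("pooled", "mean"),
                          which = "global", n_components = 2L,
                          probes = PROBE_TYPES, seed = 1L,
                          project_inputs = NULL, model = NULL,
                          reference_sites = NULL,
                          params = probe_params(),
                          fp_params = fingerprint_params(),
                          write_intermediates = TRUE) {
  if (spacing <= 0) stop("config: spacing must be > 0")
  if (min_sep < spacing) stop("config: min_sep must be >= spacing")
  stopifnot(margin >= 0, k_per_probe >= 1, m_max >= 1, n_components >= 1,
            all(probes %in% PROBE_TYPES))
  which <- match.arg(which, c(PROBE_TYPES, "global"))
  weight_mode <- match.arg(weight_mode)
  global_mode <- match.arg(global_mode)
  if (is.character(inputs)) {
    missing <- inputs[!file.exists(inputs)]
    if (length(missing))
      stop("config: missing input file(s): ", paste(missing, collapse = ", "))
  }
  n_in <- length(inputs)
  if (is.null(model) && n_in < 2L)
    stop("config: need at least 2 input structures to fit a map")
  if (!is.null(model) && n_in < 1L)
    stop("config: need at least 1 structure to project")
  if (!is.null(model) && is.null(reference_sites))
    stop("config: projecting onto an existing model needs reference_sites")
  structure(list(inputs = inputs, out_dir = out_dir, spacing = spacing,
                 margin = margin, k_per_probe = as.integer(k_per_probe),
                 min_sep = min_sep, energy_cut = energy_cut,
                 weight_mode = weight_mode, global_mode = global_mode,
                 m_max = as.integer(m_max),
                 max_poses = as.integer(max_poses), which = which,
                 n_components = as.integer(n_components), probes = probes,
                 seed = as.integer(seed), project_inputs = project_inputs,
                 model = model, reference_sites = reference_sites,
                 params = params, fp_params = fp_params,
                 write_intermediates = write_intermediates),
            class = "biogps_config")
}

#' Read a pipeline configuration from YAML
#' @param path YAML file whose keys match the arguments of
#'   [biogps_config()] (parameter overrides under `params:` are applied to
#'   the defaults).
#' @return A validated `biogps_config`.
#' @export
read_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$params)) y$params <- do.call(probe_params, y$params)
  if (!is.null(y$fp_params)) y$fp_params <- do.call(fingerprint_params,
                                                    y$fp_params)
  do.call(biogps_config, y)
}

load_structures <- function(inputs) {
  if (is.list(inputs)) return(inputs)
  lapply(inputs, read_pdb)
}

#' Run the full pipeline
#'
#' Executes every stage for each input structure (failures are logged and
#' the structure skipped; the run aborts only if fewer than two survive),
#' assembles the five similarity matrices, fits the PCA map (or reuses the
#' supplied model) and optionally projects extra structures. All outputs —
#' pocket and field grids, fingerprints, matrices, `model.json`, `map.tsv`,
#' `projections.tsv` — are written under `out_dir` together with
#' `manifest.tsv` holding an md5 checksum per file.
#'
#' @param cfg A `biogps_config` (or path to a YAML config).
#' @param verbose Log stage progress to stderr.
#' @return Invisibly, a list with `sites`, `simmat`, `model`, `map`,
#'   `projections` and the `manifest` data frame.
#' @export
run_pipeline <- function(cfg, verbose = TRUE) {
  if (is.character(cfg)) cfg <- read_config(cfg)
  stopifnot(inherits(cfg, "biogps_config"))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (verbose) message(sprintf(...))
  outputs <- character(0)
  emit <- function(f) outputs <<- c(outputs, f)

  structures <- load_structures(cfg$inputs)
  sites <- list(); skipped <- character(0)
  for (s in structures) {
    say("characterizing %s", s$id)
    site <- tryCatch(
      characterize_site(s, params = cfg$params, fp_params = cfg$fp_params,
                        k_per_probe = cfg$k_per_probe,
                        min_sep = cfg$min_sep, energy_cut = cfg$energy_cut,
                        weight_mode = cfg$weight_mode, probes = cfg$probes,
                        pocket_args = list(spacing = cfg$spacing,
                                           margin = cfg$margin)),
      error = function(e) e)
    if (inherits(site, "error")) {
      say("  skipped %s: %s", s$id, conditionMessage(site))
      skipped <- c(skipped, s$id)
      next
    }
    sites[[s$id]] <- site
    if (cfg$write_intermediates) {
      pdir <- file.path(cfg$out_dir, "sites")
      dir.create(pdir, showWarnings = FALSE)
      emit(write_dx(site$pocket, NULL,
                    file.path(pdir, paste0(s$id, "_pocket.dx"))))
      for (pr in cfg$probes) {
        g <- site$pocket$grid
        vals <- numeric(prod(g$dim))
        vals[site$pocket$idx] <- site$fields[[pr]]$energy
        emit(write_dx(g, vals,
                      file.path(pdir, sprintf("%s_field_%s.dx", s$id, pr))))
      }
      emit(write_fingerprint(site$fingerprint,
                             file.path(pdir, paste0(s$id, "_fingerprint.json"))))
    }
  }

  model <- cfg$model
  if (is.character(model)) model <- read_upca(model)
  simmat <- NULL; map <- NULL; projections <- NULL

  if (is.null(model)) {
    if (length(sites) < 2L)
      stop("run_pipeline: fewer than 2 structures survived (skipped: ",
           paste(skipped, collapse = ", "), ")")
    say("comparing %d sites all against all", length(sites))
    simmat <- all_against_all(unname(sites), m_max = cfg$m_max,
                              max_poses = cfg$max_poses,
                              global_mode = cfg$global_mode)
    for (f in write_simmat(simmat, cfg$out_dir)) emit(f)
    model <- fit_upca(simmat, cfg$which, cfg$n_components)
    emit(write_upca(model, file.path(cfg$out_dir, "model.json")))
    map <- model$embedding
    utils::write.table(map, file.path(cfg$out_dir, "map.tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
    emit(file.path(cfg$out_dir, "map.tsv"))
    references <- unname(sites)
  } else {
    references <- cfg$reference_sites
    map <- model$embedding
  }

  proj_in <- cfg$project_inputs
  if (is.null(proj_in) && !is.null(cfg$model)) proj_in <- cfg$inputs
  if (!is.null(proj_in)) {
    rows <- list()
    for (s in load_structures(proj_in)) {
      say("projecting %s", s$id)
      site <- if (!is.null(sites[[s$id]])) sites[[s$id]] else
        characterize_site(s, params = cfg$params, fp_params = cfg$fp_params,
                          k_per_probe = cfg$k_per_probe,
                          min_sep = cfg$min_sep, energy_cut = cfg$energy_cut,
                          weight_mode = cfg$weight_mode, probes = cfg$probes,
                          pocket_args = list(spacing = cfg$spacing,
                                             margin = cfg$margin))
      rows[[s$id]] <- project_site(model, site, references,
                                   m_max = cfg$m_max,
                                   max_poses = cfg$max_poses)
    }
    projections <- do.call(rbind, rows); rownames(projections) <- NULL
    utils::write.table(projections,
                       file.path(cfg$out_dir, "projections.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    emit(file.path(cfg$out_dir, "projections.tsv"))
  }

  settings <- cfg[c("spacing", "margin", "k_per_probe", "min_sep",
                    "energy_cut", "weight_mode", "global_mode", "m_max",
                    "max_poses", "which", "n_components", "probes", "seed")]
  settings$package_version <- as.character(utils::packageVersion("biogps"))
  settings$skipped <- skipped
  cfg_file <- file.path(cfg$out_dir, "run_config.json")
  writeLines(jsonlite::toJSON(settings, auto_unbox = TRUE, digits = NA),
             cfg_file)
  emit(cfg_file)

  manifest <- data.frame(file = sub(paste0("^", cfg$out_dir, "/?"), "",
                                    outputs),
                         md5 = unname(tools::md5sum(outputs)),
                         stringsAsFactors = FALSE)
  utils::write.table(manifest, file.path(cfg$out_dir, "manifest.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  say("wrote %d artifacts to %s", nrow(manifest), cfg$out_dir)
  invisible(list(sites = sites, simmat = simmat, model = model, map = map,
                 projections = projections, manifest = manifest))
}
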