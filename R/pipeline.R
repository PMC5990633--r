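#' Read and validate a cohort configuration
#'
#' YAML schema: a `subjects` list of entries with `mesh` (surface path),
#' `sphere` (spherical parameterization path), optional `constraint`
#' (`.gii` label or `.txt` index list), optional `sulci` (list of sulcal
#' line JSON paths) and optional `reference` (reference parcellation
#' `.gii` for significance testing); plus a `parameters` map with
#' `n_clusters`, optional `n_eigs`, `seed`, `n_rot`, `mode`
#' (`"group"` or `"individual"`) and `template_subdivisions`.  All
#' referenced files must exist and be index-consistent per subject; this is
#' checked before any computation.
#'
#' @param config path to a YAML file, or an equivalent named list.
#' @return validated config list of class `cohort_config`.
#' @export
read_cohort_config <- function(config) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  if (is.null(cfg$subjects) || length(cfg$subjects) == 0L)
    stop("cohort config needs a nonempty `subjects` list")
  p <- cfg$parameters
  if (is.null(p$n_clusters)) stop("parameters$n_clusters is required")
  defaults <- list(n_eigs = NULL, seed = 0L, n_rot = 500L, mode = "group",
                   template_subdivisions = 3L, restarts = 20L)
  for (nm in names(defaults))
    if (is.null(p[[nm]])) p[[nm]] <- defaults[[nm]]
  p$mode <- match.arg(p$mode, c("group", "individual"))
  cfg$parameters <- p
  for (i in seq_along(cfg$subjects)) {
    s <- cfg$subjects[[i]]
    for (f in c(s$mesh, s$sphere, s$constraint, s$reference, unlist(s$sulci)))
      if (!file.exists(f)) stop("subject ", i, ": file not found: ", f)
    if (is.null(s$mesh) || is.null(s$sphere))
      stop("subject ", i, ": `mesh` and `sphere` are required")
  }
  structure(cfg, class = "cohort_config")
}

load_subject <- function(entry, n_eigs) {
  mesh <- read_surface(entry$mesh)
  assert_valid_mesh(mesh)
  param <- read_sphere(entry$sphere)
  if (nrow(param$sphere_vertices) != nrow(mesh$vertices))
    stop("sphere/mesh vertex counts differ")
  constraint <- NULL
  if (!is.null(entry$constraint)) {
    constraint <- if (grepl("\\.gii$", entry$constraint)) {
      m <- read_labels_gifti(entry$constraint)
      constraint_region(which(m$labels != 0L), nrow(mesh$vertices))
    } else read_index_list(entry$constraint, nrow(mesh$vertices))
  }
  sulci <- lapply(entry$sulci, read_sulcal_line, mesh = mesh)
  reference <- if (!is.null(entry$reference))
    read_labels_gifti(entry$reference) else NULL
  fem <- assemble_fem(mesh)
  basis <- compute_spectrum(fem, n_eigs)
  list(mesh = mesh, param = param, constraint = constraint, sulci = sulci,
       reference = reference, basis = basis, name = basename(entry$mesh))
}

#' Run the full cohort pipeline
#'
#' Orchestrates spectrum computation, sign alignment on a common icosphere
#' template, individual or group spectral parcellation, Hungarian label
#' matching to the first (reference) subject, consensus mapping, partition
#' metrics and, when reference parcellations are supplied, the
#' rotation-null significance test.  Per-subject failures are quarantined
#' and reported; the cohort run continues with the remaining subjects.  All
#' randomness derives from `parameters$seed` through a fixed per-stage
#' scheme, so reruns with one seed are identical.
#'
#' @param config a path, list, or `cohort_config` (see
#'   [read_cohort_config()]).
#' @param out_dir optional directory; when given, per-subject label GIFTIs
#'   and `report.json` are written there.
#' @return report list of class `cohort_report`: per-subject label vectors
#'   and file paths, pairwise rand distances, per-region Dice against the
#'   reference subject, sulcus distances, significance summaries, and
#'   parameter/seed provenance.
#' @export
run_cohort <- function(config, out_dir = NULL) {
  cfg <- if (inherits(config, "cohort_config")) config else
    read_cohort_config(config)
  p <- cfg$parameters
  constrained_any <- any(vapply(cfg$subjects,
                                function(s) !is.null(s$constraint), TRUE))
  n_eigs <- if (!is.null(p$n_eigs)) p$n_eigs else
    if (constrained_any) p$n_clusters + 1L else p$n_clusters
  template <- make_icosphere(p$template_subdivisions)$param

  subjects <- list()
  failures <- list()
  for (i in seq_along(cfg$subjects)) {
    res <- tryCatch(load_subject(cfg$subjects[[i]], n_eigs),
                    error = function(e) e)
    if (inherits(res, "error")) {
      failures[[length(failures) + 1L]] <-
        list(subject = i, error = conditionMessage(res))
    } else subjects[[length(subjects) + 1L]] <- res
  }
  if (length(subjects) == 0L) stop("no subject loaded successfully")
  S <- length(subjects)

  bases <- sign_align(lapply(subjects, `[[`, "basis"),
                      lapply(subjects, `[[`, "param"), template)
  constraints <- lapply(subjects, `[[`, "constraint")

  if (p$mode == "group") {
    maps <- group_spectral_parcellate(bases, p$n_clusters,
                                      constraints = constraints,
                                      n_eigs_used = n_eigs,
                                      seed = derive_seed(p$seed, 1L),
                                      restarts = p$restarts)
  } else {
    maps <- lapply(seq_len(S), function(s)
      spectral_parcellate(subjects[[s]]$mesh, bases[[s]], p$n_clusters,
                          n_eigs_used = n_eigs,
                          constraint = constraints[[s]],
                          seed = derive_seed(p$seed, 100L + s),
                          restarts = p$restarts))
  }
  on_template <- lapply(seq_len(S), function(s)
    resample_to_template(maps[[s]], subjects[[s]]$param, template))
  if (p$mode == "individual" && S > 1L) {
    for (s in seq_len(S)[-1L]) {
      rel <- match_labels(contingency(on_template[[1L]], on_template[[s]]))
      maps[[s]] <- apply_relabeling(maps[[s]], rel)
      on_template[[s]] <- apply_relabeling(on_template[[s]], rel)
    }
  }
  cons <- consensus(on_template)

  pairwise_rand <- matrix(0, S, S)
  for (a in seq_len(S)) for (b in seq_len(S)) if (a < b)
    pairwise_rand[a, b] <- pairwise_rand[b, a] <-
      rand_distance(contingency(on_template[[a]], on_template[[b]]))$rand_distance

  dice_vs_ref <- lapply(seq_len(S), function(s)
    dice_per_label(on_template[[1L]], on_template[[s]],
                   match_labels(contingency(on_template[[1L]],
                                            on_template[[s]]))))

  sulcus <- lapply(seq_len(S), function(s) {
    if (length(subjects[[s]]$sulci) == 0L) return(NULL)
    fg <- fiedler_extremal_geodesic(subjects[[s]]$mesh, bases[[s]])
    lapply(subjects[[s]]$sulci, function(line) {
      r <- sulcus_boundary_distance(subjects[[s]]$mesh, line, maps[[s]],
                                    normalizer = fg$length_mm)
      list(label = line$label, mean_mm = r$mean_mm, percent = r$percent)
    })
  })

  significance <- lapply(seq_len(S), function(s) {
    ref <- subjects[[s]]$reference
    if (is.null(ref)) return(NULL)
    ref_t <- resample_to_template(ref, subjects[[s]]$param, template)
    st <- significance_test(on_template[[s]], ref_t, template,
                            n_rot = p$n_rot,
                            seed = derive_seed(p$seed, 200L + s))
    list(observed = st$observed, p_value = st$p_value,
         null_min = min(st$null_distances),
         null_median = stats::median(st$null_distances),
         null_max = max(st$null_distances), n_rot = st$n_rot)
  })

  sul_mm <- unlist(lapply(sulcus, function(ss)
    vapply(ss, `[[`, 0, "mean_mm")))
  report <- list(
    schema_version = "1.0",
    package_version = as.character(utils::packageVersion("spanol")),
    parameters = p[c("n_clusters", "seed", "n_rot", "mode",
                     "template_subdivisions", "restarts")],
    n_eigs = n_eigs,
    n_subjects = S,
    subject_names = vapply(subjects, `[[`, "", "name"),
    failures = failures,
    labels = lapply(maps, `[[`, "labels"),
    pairwise_rand = pairwise_rand,
    dice_vs_reference_subject = dice_vs_ref,
    sulcus_distances = sulcus,
    sulcus_summary = if (length(sul_mm))
      list(median_mm = stats::median(sul_mm), min_mm = min(sul_mm),
           max_mm = max(sul_mm)) else NULL,
    significance = significance,
    consensus_labels = cons$map$labels)

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    for (s in seq_len(S)) {
      f <- file.path(out_dir, sprintf("subject%02d.label.gii", s))
      write_labels_gifti(maps[[s]], f)
    }
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  structure(report, class = "cohort_report")
}

#' @export
print.cohort_report <- function(x, ...) {
  cat(sprintf("cohort_report: %d subjects, mode=%s, K=%d (%d eigenvectors)\n",
              x$n_subjects, x$parameters$mode, x$parameters$n_clusters,
              x$n_eigs))
  if (x$n_subjects > 1L)
    cat(sprintf("  median pairwise rand distance: %.4g\n",
                stats::median(x$pairwise_rand[upper.tri(x$pairwise_rand)])))
  if (length(x$failures))
    cat("  failures:", length(x$failures), "subject(s)\n")
  invisible(x)
}
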