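# End-to-end analysis: descriptors -> ordinations -> Pmax -> Protest matrix
# -> homogenized-variance simulation -> report bundle on disk.

#' Configuration for a full analysis run
#'
#' @param input a [grouped_dataset()] or the path of a Fourier-coefficient
#'   table (see [read_fc_table()]).
#' @param out_dir output directory (created if needed).
#' @param n_axes ordination axes retained for configurations (default 4).
#' @param n_boot Pmax bootstrap replicates (default 100).
#' @param n_perm Protest permutations (default 999).
#' @param n_sim simulation replicates (default 999).
#' @param seed root RNG seed.
#' @param pmax_min_n minimum group size for the Pmax report (default 30).
#' @param distance_matrix optional labeled square matrix (or file path for
#'   [read_distance_matrix()]): an external configuration, e.g. genetic
#'   distances, embedded by [pcoa()] and compared to each morphometric
#'   ordination.
#' @param group_map optional named character vector relabelling groups
#'   (`old = "new"`) before analysis; groups mapped to `NA` are dropped.
#'   Supports merged/averaged designs such as country-level regroupings.
#' @param simulation_groups optional subset of groups for the simulation
#'   study (default: all).
#' @param plots write PDF figures (default TRUE).
#' @return an object of class `analysis_config`.
#' @export
analysis_config <- function(input, out_dir, n_axes = 4L, n_boot = 100L,
                            n_perm = 999L, n_sim = 999L, seed = 1L,
                            pmax_min_n = 30L, distance_matrix = NULL,
                            group_map = NULL, simulation_groups = NULL,
                            plots = TRUE) {
  if (n_axes < 2L) stop("`n_axes` must be >= 2", call. = FALSE)
  if (min(n_boot, n_perm, n_sim) < 1L)
    stop("replicate counts must be positive", call. = FALSE)
  structure(list(input = input, out_dir = out_dir, n_axes = as.integer(n_axes),
                 n_boot = as.integer(n_boot), n_perm = as.integer(n_perm),
                 n_sim = as.integer(n_sim), seed = as.integer(seed),
                 pmax_min_n = as.integer(pmax_min_n),
                 distance_matrix = distance_matrix,
                 group_map = group_map,
                 simulation_groups = simulation_groups,
                 plots = isTRUE(plots)),
            class = "analysis_config")
}

.stage <- function(name, out_dir, expr) {
  message("[shapevar] stage: ", name)
  tryCatch(expr, error = function(e) {
    writeLines(paste0("FAILED at stage: ", name, "\n", conditionMessage(e)),
               file.path(out_dir, "FAILED"))
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
  })
}

.write_tsv <- function(x, path, rowname_col = NULL) {
  if (!is.null(rowname_col)) {
    x <- data.frame(stats::setNames(list(rownames(x)), rowname_col),
                    x, check.names = FALSE)
  }
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Run the full differentiation analysis
#'
#' Sequences the whole study design on one dataset: the three ordinations
#' (PCA, bgPCA, CVA) with eigenvalue/percent tables, scores and group-mean
#' configurations; the pairwise Protest table among the three methods (plus
#' a PCoA of an external distance matrix, if given); the Pmax report for
#' all well-sampled groups with pairwise bootstrap comparisons; the
#' homogenized-variance simulation study; and a JSON manifest with the seed
#' and configuration, sufficient to re-run identically. All outputs are
#' tab-delimited text under `config$out_dir`; a failing stage aborts with
#' the stage name and leaves a `FAILED` marker next to any partial outputs.
#'
#' @param config an [analysis_config()].
#' @return (invisibly) a list with elements `data`, `ordinations`,
#'   `protest`, `pmax`, `pmax_comparisons`, `simulation`, `manifest`.
#' @export
run_full_analysis <- function(config) {
  stopifnot(inherits(config, "analysis_config"))
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  unlink(file.path(out, "FAILED"))

  data <- .stage("read-input", out, {
    d <- if (inherits(config$input, "grouped_dataset")) config$input
         else read_fc_table(config$input)
    if (!is.null(config$group_map)) {
      lab <- as.character(d$groups)
      mapped <- ifelse(lab %in% names(config$group_map),
                       config$group_map[lab], lab)
      keep <- !is.na(mapped)
      d <- grouped_dataset(d$values[keep, , drop = FALSE], mapped[keep])
    }
    d
  })

  ords <- .stage("ordinations", out, {
    if (nrow(data$values) - nlevels(data$groups) < ncol(data$values))
      stop("CVA requires n - g >= p (n = ", nrow(data$values),
           ", g = ", nlevels(data$groups), ", p = ", ncol(data$values), ")")
    o <- list(PCA = pca(data, config$n_axes),
              bgPCA = bgpca(data, config$n_axes),
              CVA = cva(data, config$n_axes))
    for (m in names(o)) {
      .write_tsv(data.frame(axis = seq_along(o[[m]]$eigenvalues),
                            eigenvalue = o[[m]]$eigenvalues,
                            percent_variance = o[[m]]$percent_variance),
                 file.path(out, paste0(tolower(m), "_eigen.tsv")))
      .write_tsv(group_config(o[[m]], config$n_axes),
                 file.path(out, paste0(tolower(m), "_group_config.tsv")),
                 rowname_col = "group")
      .write_tsv(o[[m]]$scores,
                 file.path(out, paste0(tolower(m), "_scores.tsv")))
    }
    o
  })

  prot <- .stage("protest", out, {
    cfgs <- lapply(ords, group_config, n_axes = config$n_axes)
    if (!is.null(config$distance_matrix)) {
      dm <- config$distance_matrix
      if (is.character(dm)) dm <- read_distance_matrix(dm)
      cfgs$PCoA <- group_config(pcoa(dm, config$n_axes), config$n_axes)
    }
    pairs <- utils::combn(names(cfgs), 2L)
    tab <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(i) {
      a <- pairs[1L, i]; b <- pairs[2L, i]
      common <- intersect(rownames(cfgs[[a]]), rownames(cfgs[[b]]))
      pr <- protest(cfgs[[a]][common, , drop = FALSE],
                    cfgs[[b]][common, , drop = FALSE],
                    n_perm = config$n_perm, seed = config$seed)
      data.frame(x = a, y = b, n_groups = length(common),
                 d = pr$d, r = pr$r, p_value = pr$p_value)
    }))
    .write_tsv(tab, file.path(out, "protest.tsv"))
    tab
  })

  pmx <- .stage("pmax", out, {
    sizes <- table(data$groups)
    well <- names(sizes)[sizes >= config$pmax_min_n]
    ests <- lapply(well, function(g) {
      bootstrap_pmax(data$values[data$groups == g, , drop = FALSE],
                     n_boot = config$n_boot, seed = config$seed,
                     group_id = g, min_n = config$pmax_min_n)
    })
    names(ests) <- well
    comps <- NULL
    if (length(well) >= 2L) {
      pairs <- utils::combn(well, 2L)
      comps <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(i) {
        cm <- compare_pmax(ests[[pairs[1L, i]]], ests[[pairs[2L, i]]])
        data.frame(group_a = cm$group_a, group_b = cm$group_b,
                   r_between = cm$r_between, threshold = cm$threshold,
                   distinguishable = cm$distinguishable)
      }))
      .write_tsv(comps, file.path(out, "pmax_comparisons.tsv"))
    }
    if (length(ests)) {
      .write_tsv(data.frame(group = well,
                            n = as.vector(sizes[well]),
                            percent_lambda1 = vapply(ests, `[[`,
                              numeric(1L), "percent_first_eigenvalue"),
                            r95 = vapply(ests, `[[`, numeric(1L), "r95")),
                 file.path(out, "pmax_report.tsv"))
      .write_tsv(t(vapply(ests, `[[`,
                          numeric(ncol(data$values)), "loading_vector")),
                 file.path(out, "pmax_loadings.tsv"), rowname_col = "group")
    }
    list(estimates = ests, comparisons = comps)
  })

  sim <- .stage("simulation", out, {
    s <- simulation_study(data, n_sim = config$n_sim,
                          n_axes = config$n_axes, seed = config$seed,
                          groups = config$simulation_groups)
    .write_tsv(data.frame(pair = names(s$observed_d),
                          observed_d = s$observed_d,
                          observed_quantile = s$observed_quantile,
                          sim_mean_d = colMeans(s$simulated_d),
                          sim_q975 = apply(s$simulated_d, 2L,
                                           stats::quantile, 0.975)),
               file.path(out, "simulation_summary.tsv"))
    .write_tsv(s$simulated_d, file.path(out, "simulation_distances.tsv"))
    s
  })

  if (config$plots) {
    .stage("plots", out, {
      grDevices::pdf(file.path(out, "figures.pdf"), width = 10, height = 4)
      on.exit(grDevices::dev.off())
      plot(sim)
      graphics::par(mfrow = c(1L, 3L))
      for (m in names(ords)) {
        gc <- group_config(ords[[m]], config$n_axes)
        graphics::plot(gc[, 1L], gc[, 2L], pch = 19, main = m,
                       xlab = colnames(gc)[1L], ylab = colnames(gc)[2L])
        graphics::text(gc[, 1L], gc[, 2L], rownames(gc), pos = 3, cex = 0.7)
      }
      NULL
    })
  }

  manifest <- list(
    package = "shapevar",
    version = as.character(utils::packageVersion("shapevar")),
    r_version = R.version.string,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = config$seed,
    n_axes = config$n_axes, n_boot = config$n_boot,
    n_perm = config$n_perm, n_sim = config$n_sim,
    pmax_min_n = config$pmax_min_n,
    input = if (is.character(config$input)) config$input else "<in-memory>",
    groups = levels(data$groups),
    group_sizes = as.list(table(data$groups)))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)

  invisible(list(data = data, ordinations = ords, protest = prot,
                 pmax = pmx, simulation = sim, manifest = manifest))
}
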