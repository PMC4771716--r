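#' Describe the column layout of a site table
#'
#' The pipeline consumes one flat table: planar coordinates, environmental
#' covariates (in named groups, used later for variation partitioning), and
#' species counts, all row-aligned by a unique site id. The default layout
#' matches [sim_site_table()].
#'
#' @param id Site id column.
#' @param coords The two coordinate columns (projected units, km).
#' @param species Species count columns.
#' @param env_groups Named list of environmental column groups (e.g.
#'   temperature, land use, distance). Group names label the variation
#'   partitioning fractions.
#' @return A list of class `site_schema`.
#' @export
site_schema <- function(id = "site_id",
                        coords = c("x_km", "y_km"),
                        species = c("hhalys", "chilaris", "eservus"),
                        env_groups = list(
                          temperature = c("mayT", "junT", "julT", "augT"),
                          landuse = as.vector(outer(
                            c("forestdeci", "forestever", "forestother",
                              "developopen", "cropscornsoy"),
                            c("250", "500", "1k", "2k", "3k", "5k", "10k"),
                            paste0)),
                          distance = "dist_km")) {
  if (length(coords) != 2) abort("`coords` must name exactly two columns")
  if (length(species) < 1) abort("`species` must name at least one column")
  structure(list(id = id, coords = coords, species = species,
                 env_groups = env_groups,
                 env = unlist(env_groups, use.names = FALSE)),
            class = "site_schema")
}

#' Read and validate a site table CSV
#'
#' Checks that every schema column is present and numeric (ids excepted),
#' that site ids are unique, and that no cell is missing; offending columns
#' and rows are named in the error.
#'
#' @param path CSV file path.
#' @param schema A [site_schema()].
#' @return A validated tibble.
#' @export
read_site_table <- function(path, schema = site_schema()) {
  if (!file.exists(path)) abort(sprintf("no such file: %s", path))
  sites <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  validate_site_table(sites, schema)
}

validate_site_table <- function(sites, schema = site_schema()) {
  stopifnot(inherits(schema, "site_schema"))
  need <- c(schema$id, schema$coords, schema$env, schema$species)
  missing <- setdiff(need, names(sites))
  if (length(missing) > 0) {
    abort(sprintf("site table is missing column(s): %s",
                  paste(missing, collapse = ", ")))
  }
  ids <- sites[[schema$id]]
  if (anyDuplicated(ids)) {
    abort(sprintf("duplicated site id(s): %s",
                  paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  }
  num_cols <- c(schema$coords, schema$env, schema$species)
  bad <- num_cols[!vapply(sites[num_cols], is.numeric, logical(1))]
  if (length(bad) > 0) {
    abort(sprintf("non-numeric column(s): %s", paste(bad, collapse = ", ")))
  }
  na_rows <- which(rowSums(is.na(sites[num_cols])) > 0)
  if (length(na_rows) > 0) {
    abort(sprintf("missing values in row(s): %s",
                  paste(head(na_rows, 10), collapse = ", ")))
  }
  sites
}

#' Analysis settings for the end-to-end pipeline
#'
#' @param nperm Permutations for every permutation test (default 999).
#' @param n_groups Smoothed scalogram components (default 8).
#' @param alpha Forward-selection significance level (default 0.05).
#' @param axes Ordination axes fed to scalograms (default first two).
#' @param emphases Which community emphases to run: `"abundant"` applies
#'   the Hellinger transformation, `"rare"` the chi-square transformation.
#' @param mem_detrended If TRUE, forward-select MEMs on the residuals of
#'   the selected environmental model rather than on the raw transformed
#'   table (default FALSE: raw table).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(nperm = 999, n_groups = 8, alpha = 0.05,
                            axes = 1:2,
                            emphases = c("abundant", "rare"),
                            mem_detrended = FALSE) {
  emphases <- match.arg(emphases, several.ok = TRUE)
  structure(list(nperm = nperm, n_groups = n_groups, alpha = alpha,
                 axes = axes, emphases = emphases,
                 mem_detrended = mem_detrended),
            class = "pipeline_config")
}

# Scalograms for the requested axes of one ordination.
axis_scalograms <- function(ord, basis, axes, n_groups, nperm, seeds) {
  sc <- ord$scores
  axes <- axes[axes <= ncol(sc)]
  out <- list()
  for (i in seq_along(axes)) {
    out[[paste0("axis", axes[i])]] <-
      r2max_test(sc[, axes[i]], basis, n_groups = n_groups,
                 nperm = nperm, seed = seeds[i])
  }
  out
}

#' Run the full multiscale analysis on a site table
#'
#' Reproduces the analysis sequence on any conforming site table. Once per
#' table: Gabriel graph (connectivity asserted) and MEM basis. Then per
#' emphasis: community transformation (Hellinger for the abundant emphasis,
#' chi-square for the rare emphasis); PCA with scalogram + R2max test on the
#' leading axes; forward selection of environmental variables (double
#' stopping rule); RDA on the selected variables with scalograms of the
#' constrained (LC) axis scores; partial residual analysis (PRA) with
#' scalograms; forward selection of MEM spatial predictors; sign split of
#' the selected MEMs into broad-medium and fine subsets; and variation
#' partitioning, both environment-versus-space and within-environment
#' (between the schema's environmental groups).
#'
#' Because the full MEM basis spans the centred site space (saturated
#' global model), the MEM selection stage applies the permutation-alpha
#' stopping rule only; the global adjusted-R2 stop is not defined there.
#'
#' Every stage seed derives from the single `seed`, so reruns with the same
#' inputs are bit-identical.
#'
#' @param sites A site table (tibble or data frame).
#' @param schema A [site_schema()] describing it.
#' @param config A [pipeline_config()].
#' @param seed Master seed.
#' @return A `pipeline_result`: list with `graph`, `basis`, per-emphasis
#'   results (`ordinations`, `scalograms`, `selection_env`, `selection_mem`,
#'   `mem_scales`, `partitions`), and `meta`.
#' @export
run_pipeline <- function(sites, schema = site_schema(),
                         config = pipeline_config(), seed = 1) {
  stopifnot(inherits(config, "pipeline_config"))
  sites <- validate_site_table(sites, schema)
  n <- nrow(sites)
  inform(sprintf("pipeline: %d sites, %d environmental variables, %d species",
                 n, length(schema$env), length(schema$species)))

  graph <- gabriel_graph(sites, coords = schema$coords, id = schema$id)
  comp <- graph_components(graph)
  if (max(comp$component) > 1) {
    abort("Gabriel graph is disconnected; MEM analysis requires one connected graph [stage: spatial graph]")
  }
  basis <- mem_basis(graph)
  X_env <- sites[, schema$env]

  emph_res <- list()
  seeds <- derive_seeds(seed, 100L)
  s_i <- 0L
  next_seed <- function() {
    s_i <<- s_i + 1L
    seeds[s_i]
  }

  for (emph in config$emphases) {
    inform(sprintf("emphasis '%s': transform + ordinations", emph))
    Yt <- if (emph == "abundant") {
      hellinger_transform(sites, schema$species)
    } else {
      chisq_transform(sites, schema$species)
    }
    res <- list(transform = attr(Yt, "transform"))

    stage <- function(name, expr) {
      tryCatch(expr, error = function(e) {
        abort(sprintf("[stage: %s, emphasis: %s] %s", name, emph,
                      conditionMessage(e)))
      })
    }

    pca <- stage("pca", fit_pca(Yt))
    res$pca <- pca
    res$scalograms <- list(
      pca = stage("pca scalograms", axis_scalograms(
        pca, basis, config$axes, config$n_groups, config$nperm,
        c(next_seed(), next_seed()))))

    sel_env <- stage("environment selection", forward_select(
      Yt, X_env, alpha = config$alpha, nperm = config$nperm,
      seed = next_seed()))
    res$selection_env <- sel_env

    if (length(sel_env$selected) > 0) {
      X_sel <- sites[, sel_env$selected]
      rda <- stage("rda", fit_rda(Yt, X_sel))
      res$rda <- rda
      res$rda_test <- stage("rda permutation test", rda_perm_test(
        Yt, X_sel, nperm = config$nperm, seed = next_seed()))
      res$scalograms$rda <- stage("rda scalograms", axis_scalograms(
        rda, basis, config$axes, config$n_groups, config$nperm,
        c(next_seed(), next_seed())))
      pra <- stage("pra", fit_pra(Yt, X_sel))
      res$pra <- pra
      res$scalograms$pra <- stage("pra scalograms", axis_scalograms(
        pra, basis, config$axes, config$n_groups, config$nperm,
        c(next_seed(), next_seed())))
    } else {
      inform(sprintf(
        "emphasis '%s': no environmental variable retained; skipping RDA/PRA",
        emph))
    }

    mem_y <- if (config$mem_detrended && length(sel_env$selected) > 0) {
      partial_residuals(Yt, sites[, sel_env$selected])
    } else {
      Yt
    }
    # saturated global model (m = n - 1): alpha stop only
    sel_mem <- stage("MEM selection", forward_select(
      mem_y, basis$vectors, alpha = config$alpha, nperm = config$nperm,
      seed = next_seed(), global_adj_r2 = Inf, standardise = FALSE))
    res$selection_mem <- sel_mem
    mi <- basis$morans_i[match(sel_mem$selected, colnames(basis$vectors))]
    res$mem_scales <- tibble::tibble(
      mem = sel_mem$selected, morans_i = mi,
      scale = ifelse(mi > 0, "broad_medium", "fine"))

    res$partitions <- list()
    if (length(sel_env$selected) > 0 && length(sel_mem$selected) > 0) {
      subs <- list(environment = sites[, sel_env$selected])
      broad <- sel_mem$selected[mi > 0]
      fine <- sel_mem$selected[mi <= 0]
      if (length(broad) > 0) {
        subs$spatial_broad <- as.data.frame(
          basis$vectors[, broad, drop = FALSE])
      }
      if (length(fine) > 0) {
        subs$spatial_fine <- as.data.frame(
          basis$vectors[, fine, drop = FALSE])
      }
      if (length(subs) >= 2) {
        res$partitions$env_spatial <- stage(
          "environment x space partition",
          variation_partition(Yt, subs, nperm = config$nperm,
                              seed = next_seed()))
      }
    }
    env_subs <- purrr::compact(purrr::map(
      schema$env_groups, ~ {
        keep <- intersect(.x, sel_env$selected)
        if (length(keep) > 0) sites[, keep] else NULL
      }))
    if (length(env_subs) >= 2 && length(env_subs) <= 3) {
      res$partitions$within_env <- stage(
        "within-environment partition",
        variation_partition(Yt, env_subs, nperm = config$nperm,
                            seed = next_seed()))
    }
    emph_res[[emph]] <- res
  }

  structure(
    list(graph = graph, basis = basis, emphases = emph_res,
         meta = list(seed = seed, config = unclass(config),
                     n_sites = n, schema = unclass(schema),
                     package_version = as.character(
                       utils::packageVersion("memscale")))),
    class = "pipeline_result"
  )
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("Multiscale pipeline result: %d sites, %d MEMs, emphases: %s\n",
              x$meta$n_sites, ncol(x$basis$vectors),
              paste(names(x$emphases), collapse = ", ")))
  for (emph in names(x$emphases)) {
    r <- x$emphases[[emph]]
    cat(sprintf("- %s (%s): %d env vars selected, %d MEMs selected\n",
                emph, r$transform, length(r$selection_env$selected),
                length(r$selection_mem$selected)))
  }
  invisible(x)
}

# Compact JSON-safe summary of a pipeline result (no file paths, no times).
summarise_bundle <- function(bundle) {
  emph <- lapply(bundle$emphases, function(r) {
    sc <- lapply(r$scalograms, function(stage) {
      lapply(stage, function(s) {
        list(r2max = s$r2max, component = s$component, p_value = s$p_value,
             nperm = s$nperm, seed = s$seed)
      })
    })
    out <- list(
      transform = r$transform,
      pca = list(prop_axes = r$pca$prop_axes,
                 total_inertia = r$pca$total_inertia),
      scalograms = sc,
      selection_env = list(steps = r$selection_env$steps,
                           reason = r$selection_env$reason,
                           global_adj_r2 = r$selection_env$global_adj_r2),
      selection_mem = list(steps = r$selection_mem$steps,
                           reason = r$selection_mem$reason),
      mem_scales = r$mem_scales,
      partitions = lapply(r$partitions, function(p) p$fractions)
    )
    if (!is.null(r$rda)) {
      out$rda <- list(r2 = r$rda$r2, adj_r2 = r$rda$adj_r2,
                      prop_axes = r$rda$prop_axes,
                      p_value = r$rda_test$p_value)
    }
    out
  })
  list(meta = bundle$meta[c("seed", "config", "n_sites", "package_version")],
       n_mems = ncol(bundle$basis$vectors),
       emphases = emph)
}

#' Serialise a pipeline result to CSV + JSON files
#'
#' Writes, under `out_dir`: the Gabriel edge list; the MEM basis; per
#' emphasis the ordination site scores and loadings, the smoothed
#' scalograms, the selection tables (variable / order / R2 / R2Cum /
#' AdjR2Cum / F / pval layout) and partition fractions; one `summary.json`
#' with every headline number; and a `manifest.csv` listing all files.
#' Outputs contain no timestamps, so a rerun with the same seed and inputs
#' is byte-identical.
#'
#' @param bundle A [run_pipeline()] result.
#' @param out_dir Output directory (created if needed).
#' @return Tibble manifest of written files (invisibly).
#' @export
write_results <- function(bundle, out_dir) {
  stopifnot(inherits(bundle, "pipeline_result"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) abort(sprintf("cannot create directory: %s", out_dir))
  files <- character(0)
  put <- function(rel) {
    files <<- c(files, rel)
    file.path(out_dir, rel)
  }
  write_edges_csv(bundle$graph, put("gabriel_edges.csv"))
  write_mem_csv(bundle$basis, put("mem_basis.csv"))
  files <- c(files, "mem_basis.csv.json")

  for (emph in names(bundle$emphases)) {
    r <- bundle$emphases[[emph]]
    for (kind in c("pca", "rda", "pra")) {
      ord <- r[[kind]]
      if (is.null(ord)) next
      readr::write_csv(ord_scores(ord, seq_len(ncol(ord$scores))),
                       put(sprintf("%s_%s_scores.csv", emph, kind)))
      lo <- tibble::as_tibble(as.data.frame(ord$loadings))
      lo <- dplyr::bind_cols(tibble::tibble(species = rownames(ord$loadings)), lo)
      readr::write_csv(lo, put(sprintf("%s_%s_loadings.csv", emph, kind)))
    }
    for (stage in names(r$scalograms)) {
      for (ax in names(r$scalograms[[stage]])) {
        write_scalogram_csv(
          r$scalograms[[stage]][[ax]],
          put(sprintf("%s_%s_%s_scalogram.csv", emph, stage, ax)))
        files <- c(files, sprintf("%s_%s_%s_scalogram.csv.json", emph, stage, ax))
      }
    }
    write_selection_csv(r$selection_env, put(sprintf("%s_selection_env.csv", emph)))
    write_selection_csv(r$selection_mem, put(sprintf("%s_selection_mem.csv", emph)))
    for (pn in names(r$partitions)) {
      jsonlite::write_json(
        r$partitions[[pn]]$fractions,
        put(sprintf("%s_partition_%s.json", emph, pn)),
        auto_unbox = TRUE, digits = NA, dataframe = "rows")
    }
  }
  jsonlite::write_json(summarise_bundle(bundle), put("summary.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  manifest <- tibble::tibble(file = sort(unique(files)))
  readr::write_csv(manifest, file.path(out_dir, "manifest.csv"))
  inform(sprintf("wrote %d files to %s", nrow(manifest), out_dir))
  invisible(manifest)
}
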