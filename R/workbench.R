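#' Pipeline configuration
#'
#' Bundles the stage configurations, the run mode and the output directory
#' for [run_pipeline()].
#'
#' @param out_dir Output directory (created if missing).
#' @param mode One of `"screen-from-tables"` (simulate wells, QC, inhibition,
#'   hits), `"screen-from-images"` (quantify TIFFs against a plate map, then
#'   QC/hits), `"signature"` (simulate expression study, batch-correct,
#'   differential expression, retention), `"all"` (table screen + signature).
#' @param seed Master seed recorded in the manifest and pushed into the
#'   stage configs.
#' @param screen A [screen_config()].
#' @param study A [study_config()].
#' @param quant A [quant_params()].
#' @param rules A [tier_rules()].
#' @param thresholds A [de_thresholds()].
#' @param image_dir,plate_map_path Inputs for `"screen-from-images"`:
#'   directory of two-page TIFFs named `<plate>_<well>.tif` and a plate-map
#'   CSV.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir,
                            mode = c("all", "screen-from-tables",
                                     "screen-from-images", "signature"),
                            seed = 1L,
                            screen = screen_config(seed = seed),
                            study = study_config(seed = seed),
                            quant = quant_params(),
                            rules = tier_rules(),
                            thresholds = de_thresholds(),
                            image_dir = NULL, plate_map_path = NULL) {
  mode <- match.arg(mode)
  if (mode == "screen-from-images") {
    if (is.null(image_dir) || !dir.exists(image_dir)) {
      abort("`image_dir` must be an existing directory for image mode.")
    }
    if (is.null(plate_map_path) || !file.exists(plate_map_path)) {
      abort("`plate_map_path` must be an existing file for image mode.")
    }
  }
  structure(
    list(out_dir = out_dir, mode = mode, seed = as.integer(seed),
         screen = screen, study = study, quant = quant, rules = rules,
         thresholds = thresholds, image_dir = image_dir,
         plate_map_path = plate_map_path),
    class = "pipeline_config"
  )
}

table_schemas <- list(
  plate_map = c(plate = "character", well = "character", donor = "character",
                shrna_id = "character", gene = "character", role = "character"),
  wells = c(plate = "character", well = "character", donor = "character",
            shrna_id = "character", gene = "character", role = "character",
            density = "numeric", area = "integer", nuclei = "integer",
            score = "numeric"),
  inhibition = c(shrna_id = "character", gene = "character",
                 donor = "character", pct_inhibition = "numeric")
)

#' Schema-validated table I/O
#'
#' Readers check that every schema column is present with a coercible type
#' (errors name the offending column); unknown extra columns are kept with
#' a warning. Writers emit headers exactly matching the schema so outputs
#' are re-readable.
#'
#' @param path CSV path.
#' @param schema Schema name: one of `"plate_map"`, `"wells"`,
#'   `"inhibition"`.
#' @param table Data frame to write.
#' @return `read_screen_table()` returns a validated tibble;
#'   `write_screen_table()` returns `path` invisibly.
#' @export
read_screen_table <- function(path, schema) {
  spec <- table_schemas[[schema]]
  if (is.null(spec)) abort(sprintf("unknown schema '%s'", schema))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  require_columns(df, names(spec), sprintf("'%s' table", schema))
  extra <- setdiff(names(df), names(spec))
  if (length(extra)) {
    warn(sprintf("preserving unknown column(s): %s", paste(extra, collapse = ", ")))
  }
  for (col in names(spec)) {
    target <- spec[[col]]
    x <- df[[col]]
    ok <- switch(target,
      character = TRUE,
      numeric = is.numeric(x) || !anyNA(suppressWarnings(as.numeric(x))),
      integer = is.numeric(x) && all(x == round(x), na.rm = TRUE)
    )
    if (!isTRUE(ok)) {
      abort(sprintf("column '%s' of '%s' is not of type %s", col, schema, target))
    }
    df[[col]] <- switch(target, character = as.character(x),
                        numeric = as.numeric(x), integer = as.integer(x))
  }
  tibble::as_tibble(df[, c(names(spec), extra), drop = FALSE])
}

#' @rdname read_screen_table
#' @export
write_screen_table <- function(table, path, schema) {
  spec <- table_schemas[[schema]]
  if (is.null(spec)) abort(sprintf("unknown schema '%s'", schema))
  require_columns(table, names(spec), sprintf("'%s' table", schema))
  extra <- setdiff(names(table), names(spec))
  utils::write.csv(table[, c(names(spec), extra), drop = FALSE], path,
                   row.names = FALSE)
  invisible(path)
}

#' Run the end-to-end pipeline
#'
#' Executes the stages requested by the config's mode, writes every stage
#' output under `out_dir`, and returns (and writes) a run manifest carrying
#' the seed, per-stage row counts and md5 checksums of all output files.
#' Deterministic stages are byte-identical across reruns of the same
#' config.
#'
#' @param config A [pipeline_config()].
#' @return The manifest, invisibly (also written to
#'   `out_dir/manifest.json`).
#' @export
#' @examples
#' \donttest{
#' cfg <- pipeline_config(tempfile("run"), mode = "screen-from-tables",
#'                        screen = screen_config(n_donors = 2,
#'                                               wells_per_condition = 8,
#'                                               shrna_panel = default_shrna_panel()[1:3, ]))
#' mf <- run_pipeline(cfg)
#' names(mf$outputs)
#' }
run_pipeline <- function(config) {
  if (!inherits(config, "pipeline_config")) {
    abort("`config` must be a pipeline_config().")
  }
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  outputs <- list()
  emit <- function(name, obj, writer) {
    path <- file.path(config$out_dir, name)
    writer(obj, path)
    outputs[[name]] <<- list(
      path = path,
      rows = if (is.data.frame(obj)) nrow(obj) else NA_integer_,
      md5 = unname(tools::md5sum(path))
    )
    path
  }
  write_csv_plain <- function(obj, path) utils::write.csv(obj, path, row.names = FALSE)
  write_tsv_plain <- function(obj, path) {
    utils::write.table(obj, path, sep = "\t", row.names = FALSE, quote = FALSE)
  }

  run_screen_tail <- function(wells) {
    qc <- qc_screen(wells)
    emit("qc.csv", qc, write_csv_plain)
    if (any(wells$role == "test")) {
      inhib <- screen_inhibition(wells)
      emit("inhibition.csv", inhib,
           function(o, p) write_screen_table(o, p, "inhibition"))
      hits <- call_hits(inhib, config$rules)
      emit("hits.csv", hits, write_csv_plain)
      emit("hits_summary.json",
           list(n_genes = nrow(hits),
                tiers = as.list(table(hits$tier))),
           function(o, p) jsonlite::write_json(o, p, auto_unbox = TRUE))
    }
  }

  if (config$mode %in% c("all", "screen-from-tables")) {
    sim <- simulate_screen(config$screen)
    emit("plate_map.csv", sim$plate_map,
         function(o, p) write_screen_table(o, p, "plate_map"))
    emit("wells.csv", sim$wells,
         function(o, p) write_screen_table(o, p, "wells"))
    emit("truth_shrnas.csv", sim$truth$shrnas, write_csv_plain)
    run_screen_tail(sim$wells)
  }

  if (config$mode == "screen-from-images") {
    pm <- read_screen_table(config$plate_map_path, "plate_map")
    paths <- file.path(config$image_dir,
                       sprintf("%s_%s.tif", pm$plate, pm$well))
    missing <- !file.exists(paths)
    if (any(missing)) {
      abort(sprintf("missing image file(s), e.g. %s", paths[which(missing)[1]]))
    }
    wt <- quantify_wells(as.list(setNames(paths, pm$well)), config$quant)
    wells <- dplyr::bind_cols(pm, dplyr::select(wt, -"well"))
    emit("wells.csv", dplyr::select(wells, -"score_defined"),
         function(o, p) write_screen_table(o, p, "wells"))
    run_screen_tail(wells[wells$score_defined, ])
  }

  if (config$mode %in% c("all", "signature")) {
    sim <- simulate_expression_study(config$study)
    bc <- batch_correct(sim$exprs, sim$meta)
    de <- lapply(c(P0P1 = "P0P1", P4 = "P4"), function(pg) {
      keep <- sim$meta$passage == pg & !sim$meta$is_replicate
      moderated_de(bc$exprs[, sim$meta$sample_id[keep]], sim$meta[keep, ],
                   thresholds = config$thresholds)
    })
    emit("de_baseline.tsv", de$P0P1, write_tsv_plain)
    emit("de_p4.tsv", de$P4, write_tsv_plain)
    cmp <- compare_signatures(de$P0P1, de$P4)
    emit("signature_comparison.json",
         cmp[c("n_base", "n_follow", "n_overlap", "retention_pct",
               "retention_pct_reported", "pearson_r")],
         function(o, p) jsonlite::write_json(o, p, auto_unbox = TRUE,
                                             digits = NA))
  }

  manifest <- list(
    mode = config$mode,
    seed = config$seed,
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    outputs = outputs
  )
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
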