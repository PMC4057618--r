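pipeline_known_keys <- c(
  "seed", "out_dir", "proteomes", "simulate", "hits", "sites", "evalue",
  "paralog", "candidates", "annotations", "model", "knockouts",
  "augment", "augment_mode", "epsilon", "medium", "skip")

#' Validate a pipeline configuration
#'
#' Schema-checks a configuration before any stage runs: unknown keys are
#' rejected, referenced input files must exist, and stage prerequisites are
#' enforced up front (e.g. the fba stage needs a model path).
#'
#' @param config Named list, or path to a YAML file holding one.
#' @return The normalized config (invisible defaults filled in).
#' @export
validate_pipeline_config <- function(config) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  if (!is.list(config)) stop("config error: configuration must be a list")
  unknown <- setdiff(names(config), pipeline_known_keys)
  if (length(unknown))
    stop("config error: unknown key(s): ", paste(unknown, collapse = ", "))
  config$seed <- as.integer(config$seed %||% 1L)
  config$evalue <- as.numeric(config$evalue %||% 1e-5)
  config$epsilon <- as.numeric(config$epsilon %||% 1e-6)
  config$skip <- as.character(config$skip %||% character())
  bad_skip <- setdiff(config$skip, c("filter", "fba"))
  if (length(bad_skip))
    stop("config error: only the filter and fba stages may be skipped, not: ",
         paste(bad_skip, collapse = ", "))
  config$paralog <- utils::modifyList(
    list(min_bit_margin = 50, max_second_ratio = 0.9),
    config$paralog %||% list())
  if (is.null(config$out_dir)) stop("config error: out_dir is required")
  if (is.null(config$proteomes) && is.null(config$simulate))
    stop("config error: either proteomes (FASTA paths) or simulate ",
         "(generator settings) is required")
  for (p in c(config$proteomes$human_fasta, config$proteomes$yeast_fasta,
              config$hits$forward, config$hits$reverse,
              if (is.character(config$sites)) config$sites))
    if (!file.exists(p)) stop("config error: input file not found: ", p)
  if (!"fba" %in% config$skip) {
    if (is.null(config$model))
      stop("config error: fba stage enabled but no model path given ",
           "(set model:, or skip: [fba])")
    if (!file.exists(config$model))
      stop("config error: model file not found: ", config$model)
  }
  invisible(config)
}

write_stage_tsv <- function(df, path, config_hash) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# orthoflux config=", config_hash), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full pipeline
#'
#' Orchestrates the end-to-end workflow — reciprocal best hits, active-site
#' conservation, the candidate filter cascade, and the FBA knockout panel —
#' with no stage logic of its own. Each stage's table is written under
#' `out_dir` with a commented header carrying the config hash, and a run
#' manifest records per-output checksums: identical (config, inputs) yield
#' identical report bytes.
#'
#' @param config Named list or YAML path; see
#'   [validate_pipeline_config()]. Key groups: `proteomes` (paths
#'   `human_fasta`/`yeast_fasta`) or `simulate` (arguments to
#'   [simulate_proteomes()]); optional precomputed `hits`
#'   (`forward`/`reverse` tabular files, extended dialect); `sites` (TSV
#'   path with `accession`/`position`/`residue`; implied when simulating);
#'   `evalue`; `paralog` thresholds; optional `candidates` +
#'   `annotations` enabling the full cascade; `model`, `knockouts`,
#'   `augment`, `augment_mode`, `epsilon`, `medium` for the fba stage;
#'   `skip` (subset of `filter`, `fba`).
#' @return List of class `orthoflux_run`: `manifest` (config hash, per-file
#'   checksums), `pairs`, `classification`, `conservation`, `filter`
#'   (possibly `NULL`), `panel` (possibly `NULL`).
#' @export
run_all <- function(config) {
  config <- validate_pipeline_config(config)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  # hash everything that shapes the outputs; the output location does not
  hashed <- config[setdiff(sort(names(config)), "out_dir")]
  cfg_hash <- substr(unname(tools::md5sum(
    textConnection_write(yaml::as.yaml(hashed)))), 1, 12)

  # --- inputs ------------------------------------------------------------
  if (!is.null(config$simulate)) {
    sim <- do.call(simulate_proteomes,
                   c(list(seed = config$seed), config$simulate))
    human <- sim$human; yeast <- sim$yeast; sites <- sim$sites
  } else {
    human <- as.character(read_proteome(config$proteomes$human_fasta))
    yeast <- as.character(read_proteome(config$proteomes$yeast_fasta))
    sites <- NULL
  }
  if (is.character(config$sites))
    sites <- utils::read.delim(config$sites, stringsAsFactors = FALSE)

  # --- stage: rbh ---------------------------------------------------------
  if (!is.null(config$hits)) {
    fwd_hits <- read_hit_table(config$hits$forward)
    rev_hits <- read_hit_table(config$hits$reverse)
  } else {
    fwd_hits <- align_proteomes(human, yeast)
    rev_hits <- align_proteomes(yeast, human)
  }
  forward <- best_hit_per_query(fwd_hits, config$evalue)
  reverse <- best_hit_per_query(rev_hits, config$evalue)
  pairs <- reciprocal_best_hits(forward, reverse)
  classification <- classify_queries(names(human), forward, reverse)
  class_df <- data.frame(accession = names(classification$labels),
                         label = unname(classification$labels),
                         stringsAsFactors = FALSE)

  # --- stage: conserve ----------------------------------------------------
  if (is.null(sites))
    stop("data validation error in stage conserve: no active-site ",
         "annotations available")
  conservation <- conservation_report(pairs, c(human, yeast), sites)
  pair_cons <- unique(conservation[, c("human_acc", "pair_conserved")])

  # --- stage: filter ------------------------------------------------------
  filter_rep <- NULL
  if (!"filter" %in% config$skip) {
    candidates <- config$candidates %||% pairs$query_acc
    annotations <- config$annotations
    skip_stages <- if (is.null(annotations)) c("one_one_one", "pathway")
                   else character()
    filter_rep <- run_filter_cascade(
      candidates, pairs, pair_cons, fwd_hits, annotations,
      min_bit_margin = config$paralog$min_bit_margin,
      max_second_ratio = config$paralog$max_second_ratio,
      skip = skip_stages)
  }

  # --- stage: fba ---------------------------------------------------------
  panel <- NULL
  if (!"fba" %in% config$skip) {
    model <- load_model(config$model)
    if (!is.null(config$medium)) model <- set_medium(model, config$medium)
    aug <- list()
    if (!is.null(config$augment))
      aug <- list(augmented = list(
        requirements = unlist(config$augment),
        mode = config$augment_mode %||% "coefficient"))
    panel <- simulate_knockout_panel(
      model, as.character(config$knockouts %||% character()),
      augmentations = aug, epsilon = config$epsilon)
  }

  # --- reports ------------------------------------------------------------
  outputs <- c(
    pairs = write_stage_tsv(
      pairs[, c("query_acc", "subject_acc", "fwd_bitscore", "fwd_evalue")],
      file.path(config$out_dir, "pairs.tsv"), cfg_hash),
    classification = write_stage_tsv(
      class_df, file.path(config$out_dir, "classification.tsv"), cfg_hash),
    conservation = write_stage_tsv(
      conservation, file.path(config$out_dir, "conservation.tsv"), cfg_hash))
  if (!is.null(filter_rep)) {
    outputs <- c(outputs, filter = write_stage_tsv(
      filter_rep$dropped, file.path(config$out_dir, "filter_dropped.tsv"),
      cfg_hash))
  }
  if (!is.null(panel)) {
    outputs <- c(outputs, panel = write_stage_tsv(
      as.data.frame(panel), file.path(config$out_dir, "panel.tsv"), cfg_hash))
  }
  manifest <- list(
    tool = paste0("orthoflux ",
                  as.character(utils::packageVersion("orthoflux"))),
    config_hash = cfg_hash,
    seed = config$seed,
    outputs = as.list(tools::md5sum(outputs)))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  structure(list(manifest = manifest, pairs = pairs,
                 classification = class_df, conservation = conservation,
                 filter = filter_rep, panel = panel),
            class = "orthoflux_run")
}

# hash helper: write a string to a temp file for tools::md5sum
textConnection_write <- function(text) {
  f <- tempfile()
  writeLines(text, f)
  f
}

#' @export
print.orthoflux_run <- function(x, ...) {
  cat("<orthoflux_run> config", x$manifest$config_hash, "\n")
  cat("  pairs:", nrow(x$pairs), "\n")
  cat("  conserved pairs:",
      sum(unique(x$conservation[, c("human_acc", "pair_conserved")])$pair_conserved),
      "\n")
  if (!is.null(x$filter))
    cat("  filter survivors:", x$filter$counts[[length(x$filter$counts)]], "\n")
  if (!is.null(x$panel))
    cat("  panel rows:", nrow(x$panel), "\n")
  invisible(x)
}
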