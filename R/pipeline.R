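# Run configuration and the end-to-end pipeline commands.

.CONFIG_DEFAULTS <- list(
  acids = NULL, aldehydes = NULL, output_dir = ".",
  fsp3_min = 0.1, max_stereocenters = 0L, n_bits = 1024L,
  pca_components = 2L, seed = 1L, log_level = "info", strict = FALSE)

#' Build or load a run configuration
#'
#' A configuration holds the input paths, filter settings, embedding
#' settings, output directory and seed for a pipeline run. Values may come
#' from a YAML file, from arguments, or both (arguments win). Missing keys
#' take documented defaults, and each applied default is logged. A
#' configuration round-trips losslessly through [write_run_config()].
#'
#' @param path Optional YAML file.
#' @param ... Key-value overrides (`acids`, `aldehydes`, `output_dir`,
#'   `fsp3_min`, `max_stereocenters`, `n_bits`, `pca_components`, `seed`,
#'   `log_level`, `strict`).
#' @param check_paths Validate that referenced input paths exist.
#' @return `nah_config` object (a named list).
#' @export
run_config <- function(path = NULL, ..., check_paths = TRUE) {
  given <- list()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
    given <- yaml::read_yaml(path)
  }
  overrides <- list(...)
  given[names(overrides)] <- overrides
  unknown <- setdiff(names(given), names(.CONFIG_DEFAULTS))
  if (length(unknown) > 0) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  cfg <- .CONFIG_DEFAULTS
  defaulted <- setdiff(names(.CONFIG_DEFAULTS),
                       c(names(given), "acids", "aldehydes"))
  cfg[names(given)] <- given
  cfg$max_stereocenters <- as.integer(cfg$max_stereocenters)
  cfg$n_bits <- as.integer(cfg$n_bits)
  cfg$pca_components <- as.integer(cfg$pca_components)
  cfg$seed <- as.integer(cfg$seed)
  if (cfg$pca_components != 2L) {
    stop("the chemical-space embedding is two-dimensional; ",
         "pca_components must be 2", call. = FALSE)
  }
  if (cfg$log_level == "info" && length(defaulted) > 0) {
    message("config defaults applied: ",
            paste(sprintf("%s=%s", defaulted,
                          vapply(cfg[defaulted], format, character(1))),
                  collapse = ", "))
  }
  if (check_paths) {
    for (key in c("acids", "aldehydes")) {
      if (!is.null(cfg[[key]]) && !file.exists(cfg[[key]])) {
        stop(sprintf("config path '%s' does not exist: %s", key, cfg[[key]]),
             call. = FALSE)
      }
    }
  }
  structure(cfg, class = "nah_config")
}

#' Serialize a run configuration to YAML
#'
#' @param config An `nah_config`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config)[!vapply(config, is.null, logical(1))],
                   path)
  invisible(path)
}

.log_stage <- function(config, fmt, ...) {
  if (is.null(config$log_level) || config$log_level != "quiet") {
    message(sprintf(fmt, ...))
  }
}

.run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", name,
                 conditionMessage(e)), call. = FALSE)
  })
}

#' Curate inputs and enumerate the virtual library
#'
#' Reads the acid and aldehyde collections named in the configuration,
#' curates them (salt stripping, neutralization, role assignment,
#' deduplication), enumerates the two-stage virtual synthesis and writes
#' `library.sdf` plus `manifest.csv` into the output directory. An empty
#' product set is a valid outcome (warning, not an error).
#'
#' @param config An `nah_config` with `acids` and `aldehydes` set.
#' @return Invisibly, a list with `lib` and the stage `counts`.
#' @export
cmd_enumerate <- function(config) {
  stopifnot(inherits(config, "nah_config"))
  if (is.null(config$acids) || is.null(config$aldehydes)) {
    stop("config must name 'acids' and 'aldehydes' inputs", call. = FALSE)
  }
  acids_raw <- .run_stage("read", read_structures(config$acids))
  alds_raw <- .run_stage("read", read_structures(config$aldehydes))
  blocks <- .run_stage("curate", c(
    curate_blocks(acids_raw$smiles, acids_raw$id, strict = config$strict),
    curate_blocks(alds_raw$smiles, alds_raw$id, strict = config$strict)))
  # the two input files may overlap; keep one block per structure
  keys <- vapply(blocks, function(b) b$mol$canonical_key, character(1))
  blocks <- blocks[!duplicated(keys)]
  roles <- vapply(blocks, `[[`, character(1), "role")
  lib <- .run_stage("enumerate", enumerate_library(blocks))
  if (length(lib) == 0) warning("empty product set", call. = FALSE)
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  write_library_sdf(lib, file.path(config$output_dir, "library.sdf"))
  write.csv(library_manifest(lib),
            file.path(config$output_dir, "manifest.csv"), row.names = FALSE)
  counts <- c(input_records = nrow(acids_raw) + nrow(alds_raw),
              curated_acids = sum(roles == "acid"),
              curated_aldehydes = sum(roles == "aldehyde"),
              curated_other = sum(roles == "other"),
              products = length(lib))
  .log_stage(config, "enumerate: %d inputs -> %d acids + %d aldehydes -> %d products",
             counts[["input_records"]], counts[["curated_acids"]],
             counts[["curated_aldehydes"]], counts[["products"]])
  invisible(list(lib = lib, counts = counts))
}

#' Run the full design pipeline
#'
#' Chains enumerate -> descriptor filter -> fingerprints -> chemical-space
#' embedding and writes `filtered.sdf`, `embedding.csv` (id, x, y, fsp3) and
#' a funnel report into the output directory. Stage counts are logged so the
#' enumeration funnel can be reconstructed from the log alone.
#'
#' @param config An `nah_config`.
#' @return Invisibly, a list with `lib` (filtered, embedded), `model`,
#'   `coords` and `counts`.
#' @export
cmd_pipeline <- function(config) {
  enum <- cmd_enumerate(config)
  spec <- filter_spec(config$fsp3_min, config$max_stereocenters)
  filtered <- .run_stage("filter", apply_filters(enum$lib, spec))
  emb <- .run_stage("embed", embed_library(filtered))
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  write_library_sdf(emb$lib, file.path(config$output_dir, "filtered.sdf"))
  coords <- emb$coords
  coords$x <- sprintf("%.4f", coords$x)
  coords$y <- sprintf("%.4f", coords$y)
  coords$fsp3 <- sprintf("%.4f", coords$fsp3)
  write.csv(coords, file.path(config$output_dir, "embedding.csv"),
            row.names = FALSE)
  counts <- c(enum$counts, filtered = length(filtered))
  report <- c(
    "N-acylhydrazone design pipeline report",
    sprintf("  input records        %6d", counts[["input_records"]]),
    sprintf("  curated acids        %6d", counts[["curated_acids"]]),
    sprintf("  curated aldehydes    %6d", counts[["curated_aldehydes"]]),
    sprintf("  enumerated products  %6d", counts[["products"]]),
    sprintf("  after descriptor filter (Fsp3 >= %g, stereocenters <= %d) %6d",
            spec$fsp3_min, spec$max_stereocenters, counts[["filtered"]]),
    sprintf("  embedding: PC1 %.1f%% / PC2 %.1f%% of variance",
            100 * emb$model$explained_variance[1],
            100 * emb$model$explained_variance[2]))
  writeLines(report, file.path(config$output_dir, "report.txt"))
  .log_stage(config, "pipeline: %d products -> %d after filter",
             counts[["products"]], counts[["filtered"]])
  invisible(list(lib = emb$lib, model = emb$model, coords = emb$coords,
                 counts = counts))
}

#' Monoisotopic masses and adduct m/z for a set of structures
#'
#' @param input Path to a SMILES list or SDF file, or a character vector of
#'   SMILES.
#' @param adducts Adduct names (see [adduct_table()]).
#' @param output Optional CSV path.
#' @return data.frame with id, smiles, formula, monoisotopic mass and one
#'   column per requested adduct, all masses to 5 decimals.
#' @export
cmd_masscalc <- function(input, adducts = c("[M+H]+", "[M-H]-"),
                         output = NULL) {
  tab <- adduct_table()
  bad <- setdiff(gsub("−", "-", adducts), tab$name)
  if (length(bad) > 0) {
    stop("unsupported adduct(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  recs <- if (length(input) == 1 && file.exists(input)) {
    read_structures(input)
  } else {
    data.frame(smiles = input, id = sprintf("S%04d", seq_along(input)),
               line = seq_along(input), stringsAsFactors = FALSE)
  }
  cols <- c(list(id = character(0), smiles = character(0),
                 formula = character(0), monoisotopic_mass = numeric(0)),
            setNames(rep(list(numeric(0)), length(adducts)), adducts))
  out <- do.call(data.frame, c(cols, check.names = FALSE))
  for (i in seq_len(nrow(recs))) {
    mol <- mol_parse(recs$smiles[i])
    row <- c(list(id = recs$id[i], smiles = recs$smiles[i],
                  formula = mol_formula_string(mol),
                  monoisotopic_mass = round(monoisotopic_mass(mol), 5)),
             setNames(lapply(adducts, function(a) adduct_mz(mol, a)), adducts))
    out <- rbind(out, do.call(data.frame, c(row, check.names = FALSE)))
  }
  if (!is.null(output)) write.csv(out, output, row.names = FALSE)
  out
}
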