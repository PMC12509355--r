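# Configuration and tabular I/O. One YAML document describes the nucleus,
# its organelles and the calibration anchors; candidate scaffold species
# travel as a TSV with one row per species.

#' Parse the compact domain-decomposition encoding
#'
#' Domains are encoded as `kind:residues:rg_nm` triples joined by `;`, e.g.
#' `"O:120:2.1;D:80:?"`. Kind `O` is ordered, `D` disordered; an rg of `?`
#' asks for the disordered-chain scaling law to be applied.
#'
#' @param x a single encoding string (may be empty or `NA` for no domains)
#' @param laws scaling laws as from [default_scaling_laws()]
#' @return list of [domain_segment()]
#' @export
parse_domains <- function(x, laws = default_scaling_laws()) {
  if (is.null(x) || is.na(x) || !nzchar(trimws(x))) return(list())
  parts <- strsplit(trimws(x), ";", fixed = TRUE)[[1]]
  lapply(parts, function(p) {
    f <- strsplit(p, ":", fixed = TRUE)[[1]]
    if (length(f) != 3L)
      stop_config("malformed domain triple '%s' (expected kind:residues:rg)", p)
    kind <- switch(f[1], O = "ordered", D = "disordered",
                   stop_config("unknown domain kind '%s' (use O or D)", f[1]))
    n <- as.integer(f[2])
    if (identical(f[3], "?")) {
      if (kind != "disordered")
        stop_config("rg '?' is only valid for disordered domains ('%s')", p)
      rg <- rg_disordered(n, laws$disordered)
    } else {
      rg <- as.numeric(f[3])
    }
    domain_segment(kind, n, rg)
  })
}

#' Format a domain list back into its TSV encoding
#'
#' @param domains list of [domain_segment()]
#' @return a single string (empty for no domains)
#' @export
format_domains <- function(domains) {
  if (length(domains) == 0L) return("")
  paste(vapply(domains, function(d) {
    sprintf("%s:%d:%.17g", if (d$kind == "ordered") "O" else "D",
            d$n_residues, d$rg)
  }, character(1)), collapse = ";")
}

species_tsv_columns <- c("name", "class", "ibaq", "total_copies", "alpha",
                         "mw_da", "predicted_diameter_nm", "domains",
                         "organelle", "relaxed_diameter_nm",
                         "expanded_diameter_nm")

#' Read a candidate-scaffold species table
#'
#' The table is tab-separated with a header; required columns are `name`,
#' `class`, `ibaq`, `total_copies`, `alpha`, `mw_da`, `predicted_diameter_nm`
#' and `domains`; `organelle`, `relaxed_diameter_nm` and
#' `expanded_diameter_nm` are optional. `alpha` accepts the literal string
#' `inf` for exclusively localized proteins.
#'
#' @param path path to the TSV file
#' @param laws scaling laws used to resolve `?` radii of gyration
#' @return list of [protein_species()]
#' @export
read_species_tsv <- function(path, laws = default_scaling_laws()) {
  if (!file.exists(path)) stop_config("species file '%s' does not exist", path)
  tab <- read.delim(path, sep = "\t", header = TRUE,
                    colClasses = "character", check.names = FALSE)
  missing <- setdiff(setdiff(species_tsv_columns,
                             c("organelle", "relaxed_diameter_nm",
                               "expanded_diameter_nm")),
                     names(tab))
  if (length(missing))
    stop_config("species table is missing column(s): %s",
                paste(missing, collapse = ", "))
  num <- function(x) ifelse(is.na(x) | !nzchar(trimws(x)), NA_real_,
                            suppressWarnings(as.numeric(x)))
  lapply(seq_len(nrow(tab)), function(i) {
    row <- tab[i, , drop = FALSE]
    alpha_raw <- trimws(row$alpha)
    alpha <- if (tolower(alpha_raw) %in% c("inf", "infinite")) Inf
             else num(alpha_raw)
    ibaq <- num(row$ibaq)
    tc <- num(row$total_copies)
    args <- list(
      name = row$name, enrichment = alpha, mw = num(row$mw_da),
      domains = parse_domains(row$domains, laws),
      predicted_diameter = num(row$predicted_diameter_nm),
      organelle = if ("organelle" %in% names(tab) && nzchar(trimws(row$organelle)))
        row$organelle else NA_character_,
      relaxed_diameter = if ("relaxed_diameter_nm" %in% names(tab))
        num(row$relaxed_diameter_nm) else NA_real_,
      expanded_diameter = if ("expanded_diameter_nm" %in% names(tab))
        num(row$expanded_diameter_nm) else NA_real_)
    if (!is.na(tc)) args$total_copies <- tc else args$ibaq <- ibaq
    do.call(protein_species, args)
  })
}

#' Write a candidate-scaffold species table
#'
#' @param species list of [protein_species()]
#' @param path output TSV path
#' @return `path`, invisibly
#' @export
write_species_tsv <- function(species, path) {
  fmt <- function(x) if (is.null(x) || is.na(x)) "" else
    if (is.infinite(x)) "inf" else sprintf("%.17g", x)
  rows <- vapply(species, function(s) {
    paste(c(s$name, "protein",
            fmt(s$ibaq), fmt(s$total_copies), fmt(s$enrichment), fmt(s$mw),
            fmt(s$predicted_diameter), format_domains(s$domains),
            if (is.na(s$organelle)) "" else s$organelle,
            fmt(s$relaxed_diameter), fmt(s$expanded_diameter)),
          collapse = "\t")
  }, character(1))
  writeLines(c(paste(species_tsv_columns, collapse = "\t"), rows), path)
  invisible(path)
}

#' Load a full census configuration
#'
#' Reads a YAML document with keys `nucleus` (cell-level constants, all
#' optional), `organelles` (a list; each needs at least `name` and `volume`),
#' `calibration` (a list of `{protein, measured_copies, ibaq}` anchors) and
#' optionally `species_file` (a TSV path, resolved relative to the config
#' file).
#'
#' @param path path to the YAML configuration
#' @param laws scaling laws used when reading the species table
#' @return list with elements `nucleus`, `organelles`, `calibration_refs`
#'   and `species` (empty list when no `species_file` is given)
#' @export
load_config <- function(path, laws = default_scaling_laws()) {
  if (!file.exists(path)) stop_config("config file '%s' does not exist", path)
  cfg <- yaml::read_yaml(path)
  nucleus <- do.call(nucleus_model, as.list(cfg$nucleus))
  organelles <- lapply(cfg$organelles, function(o) {
    for (f in c("name", "volume"))
      if (is.null(o[[f]]))
        stop_config("organelle entry is missing required field '%s'", f)
    do.call(organelle_model, o)
  })
  check_organelle_budget(nucleus, organelles)
  refs <- lapply(cfg$calibration, function(r) {
    for (f in c("protein", "measured_copies", "ibaq"))
      if (is.null(r[[f]]))
        stop_config("calibration entry is missing required field '%s'", f)
    calibration_ref(r$protein, r$measured_copies, r$ibaq)
  })
  species <- list()
  if (!is.null(cfg$species_file)) {
    sp_path <- cfg$species_file
    if (!file.exists(sp_path))
      sp_path <- file.path(dirname(path), cfg$species_file)
    species <- read_species_tsv(sp_path, laws)
  }
  list(nucleus = nucleus, organelles = organelles,
       calibration_refs = refs, species = species)
}

#' Write a census configuration back to YAML
#'
#' @param nucleus a [nucleus_model()]
#' @param organelles list of [organelle_model()]
#' @param calibration_refs list of [calibration_ref()]
#' @param path output YAML path
#' @param species_file optional species TSV path recorded in the config
#' @return `path`, invisibly
#' @export
write_config <- function(nucleus, organelles, calibration_refs, path,
                         species_file = NULL) {
  cfg <- list(
    nucleus = unclass(nucleus),
    organelles = lapply(organelles, unclass),
    calibration = lapply(calibration_refs, unclass))
  if (!is.null(species_file)) cfg$species_file <- species_file
  yaml::write_yaml(cfg, path, precision = 17)
  invisible(path)
}

#' Write census tables and scorecards to a directory
#'
#' Writes `census.tsv` (one row per species per organelle) and, when
#' scorecards are supplied, `scorecards.json`. Numeric columns are written
#' with full precision so that a read round-trip reproduces counts exactly
#' and floats to better than 1e-9 relative.
#'
#' @param entries data frame with columns `organelle`, `species`, `class`,
#'   `copies`, `concentration_uM`, `mw_da`, `mass_density_mg_ml`
#' @param scores list of [score_card()] (may be empty)
#' @param dir output directory (created if needed)
#' @return `dir`, invisibly
#' @export
write_census_report <- function(entries, scores, dir) {
  if (!is.data.frame(entries) || nrow(entries) == 0L)
    stop_config("census entries must be a non-empty data frame")
  if (any(entries$copies < 0))
    stop_config("census entries with negative copies are not allowed")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cols <- c("organelle", "species", "class", "copies", "concentration_uM",
            "mw_da", "mass_density_mg_ml")
  out <- entries[, cols]
  txt <- vapply(seq_len(nrow(out)), function(i) {
    paste(c(out$organelle[i], out$species[i], out$class[i],
            sprintf("%.17g", out$copies[i]),
            sprintf("%.17g", out$concentration_uM[i]),
            sprintf("%.17g", out$mw_da[i]),
            sprintf("%.17g", out$mass_density_mg_ml[i])), collapse = "\t")
  }, character(1))
  writeLines(c(paste(cols, collapse = "\t"), txt),
             file.path(dir, "census.tsv"))
  if (length(scores) == 0L) {
    warning("no scorecards supplied; writing census tables only")
  } else {
    json <- lapply(unname(scores), function(s) list(
      organelle = s$organelle,
      scores = as.list(s$scores),
      nucleosome_to_protein_ratio = s$nucleosome_to_protein_ratio,
      mechanism_call = s$mechanism_call,
      passing_scenarios = s$passing_scenarios,
      cutoff = s$cutoff))
    jsonlite::write_json(json, file.path(dir, "scorecards.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(dir)
}

#' Read back a census report directory
#'
#' @param dir directory written by [write_census_report()]
#' @return list with `entries` (data frame) and `scores` (list of
#'   [score_card()]; empty if no scorecards were written)
#' @export
read_census_report <- function(dir) {
  tab <- read.delim(file.path(dir, "census.tsv"), sep = "\t",
                    header = TRUE, check.names = FALSE,
                    colClasses = c(rep("character", 3), rep("numeric", 4)))
  scores <- list()
  sc_path <- file.path(dir, "scorecards.json")
  if (file.exists(sc_path)) {
    raw <- jsonlite::read_json(sc_path)
    scores <- lapply(raw, function(s)
      score_card(s$organelle, unlist(s$scores),
                 s$nucleosome_to_protein_ratio, cutoff = s$cutoff))
  }
  list(entries = tab, scores = scores)
}
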