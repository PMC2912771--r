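#' Save and load tissue states
#'
#' Tissue states are serialized to a plain-text JSON document with
#' sections `vertices` (`[id, x, y]`), `walls` (`[id, v1, v2,
#' rest_length]`), `cells` (`id`, ordered wall ids, ordered vertex ids,
#' `last_division_direction`), `sim_time` and `rng_state`. Numbers are
#' written with 17 significant digits so a round trip is lossless to full
#' double precision, including the RNG state, which makes a resumed run
#' bit-identical to an uninterrupted one.
#'
#' @param tissue A tissue state.
#' @param path File path.
#' @return `save_tissue()` returns `path` invisibly; `load_tissue()`
#'   returns a validated tissue.
#' @export
save_tissue <- function(tissue, path) {
  nv <- n_vertices(tissue)
  doc <- list(
    format = "merisim-tissue",
    version = 1L,
    sim_time = tissue$sim_time,
    rng_state = if (is.null(tissue$rng_state)) NULL else as.integer(tissue$rng_state),
    vertices = lapply(seq_len(nv), function(i) {
      list(id = i, x = tissue$pos[i, 1L], y = tissue$pos[i, 2L])
    }),
    walls = lapply(seq_len(n_walls(tissue)), function(i) {
      list(id = i, v1 = tissue$walls$v1[i], v2 = tissue$walls$v2[i],
           rest_length = tissue$walls$rest_length[i])
    }),
    cells = lapply(seq_along(tissue$cells), function(i) {
      cl <- tissue$cells[[i]]
      list(id = i, walls = cl$ws, vertices = cl$vs,
           last_division_direction = if (is.na(cl$dir)) NULL else cl$dir)
    }))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = I(17), null = "null")
  invisible(path)
}

#' @rdname save_tissue
#' @export
load_tissue <- function(path) {
  doc <- tryCatch(jsonlite::read_json(path),
                  error = function(e) {
                    stop(sprintf("cannot parse tissue file '%s': %s", path,
                                 conditionMessage(e)), call. = FALSE)
                  })
  req <- c("format", "sim_time", "vertices", "walls", "cells")
  missing <- setdiff(req, names(doc))
  if (length(missing)) {
    stop(sprintf("tissue file '%s' is missing section(s): %s",
                 path, paste(missing, collapse = ", ")), call. = FALSE)
  }
  if (!identical(doc$format, "merisim-tissue")) {
    stop(sprintf("'%s' is not a merisim tissue file (format '%s')", path, doc$format),
         call. = FALSE)
  }
  get_num <- function(rec, field, what, id) {
    v <- rec[[field]]
    if (is.null(v) || !is.numeric(v) || !is.finite(v)) {
      stop(sprintf("invalid %s record %s: bad field '%s'", what, id, field),
           call. = FALSE)
    }
    v
  }
  nv <- length(doc$vertices)
  pos <- matrix(0, nv, 2L)
  for (rec in doc$vertices) {
    id <- get_num(rec, "id", "vertex", "?")
    pos[id, ] <- c(get_num(rec, "x", "vertex", id), get_num(rec, "y", "vertex", id))
  }
  nw <- length(doc$walls)
  v1 <- integer(nw); v2 <- integer(nw); L0 <- numeric(nw)
  for (rec in doc$walls) {
    id <- get_num(rec, "id", "wall", "?")
    v1[id] <- get_num(rec, "v1", "wall", id)
    v2[id] <- get_num(rec, "v2", "wall", id)
    L0[id] <- get_num(rec, "rest_length", "wall", id)
  }
  cells <- vector("list", length(doc$cells))
  for (rec in doc$cells) {
    id <- get_num(rec, "id", "cell", "?")
    if (is.null(rec$walls) || is.null(rec$vertices)) {
      stop(sprintf("invalid cell record %s: missing walls/vertices", id), call. = FALSE)
    }
    cells[[id]] <- list(vs = as.integer(unlist(rec$vertices)),
                        ws = as.integer(unlist(rec$walls)),
                        dir = if (is.null(rec$last_division_direction)) NA_real_
                              else as.numeric(rec$last_division_direction))
  }
  tt <- new_tissue(pos, walls = list(v1 = v1, v2 = v2, rest_length = L0),
                   cells = cells, sim_time = as.numeric(doc$sim_time),
                   rng_state = if (is.null(doc$rng_state)) NULL
                               else as.integer(unlist(doc$rng_state)))
  validate_tissue(tt)
  tt
}

#' Load model parameters from a configuration file
#'
#' Reads a YAML (or JSON) configuration whose keys mirror the model
#' parameter names (`spring_k`, `growth_k`, `radial_k`, `area_threshold`,
#' `d_threshold`, `radius_threshold`, plus the solver/mode fields of
#' [model_params()]). Missing keys default to the standard simulation
#' values. `preset: oryzalin` (or `load_params(preset = "oryzalin")`)
#' disables division and boundary removal, leaving the unused thresholds
#' at their defaults.
#'
#' @param path Path to a YAML/JSON config, or `NULL` for defaults only.
#' @param preset `"standard"` or `"oryzalin"`.
#' @return A [model_params()] object.
#' @export
load_params <- function(path = NULL, preset = c("standard", "oryzalin")) {
  preset <- match.arg(preset)
  cfg <- list()
  if (!is.null(path)) {
    cfg <- yaml::read_yaml(path)
    if (is.null(cfg)) cfg <- list()
    if (!is.null(cfg$preset)) {
      preset <- match.arg(cfg$preset, c("standard", "oryzalin"))
      cfg$preset <- NULL
    }
  }
  known <- names(formals(model_params))
  bad <- setdiff(names(cfg), known)
  if (length(bad)) {
    stop(sprintf("unknown parameter(s) in config: %s", paste(bad, collapse = ", ")),
         call. = FALSE)
  }
  p <- do.call(model_params, cfg)
  if (preset == "oryzalin") {
    p$division_enabled <- FALSE
    p$removal_enabled <- FALSE
  }
  p
}

#' Write a Table-1-style summary report
#'
#' Emits the per-rule aggregate statistics as a TSV table (one row per
#' rule, sorted by deviation ascending) plus a JSON summary carrying the
#' same numbers and the metadata needed to reproduce them (seed, deviation
#' metric).
#'
#' @param summaries A tibble of per-rule rows as produced by
#'   [aggregate_stats()] (bind rows across rules).
#' @param dir Output directory (created if needed).
#' @param seed Seed echoed into the JSON metadata.
#' @param deviation_method Metric label echoed into the metadata.
#' @return Invisibly, the paths written.
#' @export
emit_report <- function(summaries, dir, seed = NA_integer_,
                        deviation_method = "sq") {
  stopifnot(nrow(summaries) >= 1L)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  out <- summaries[order(summaries$deviation_mean), ]
  tsv <- file.path(dir, "rule_summary.tsv")
  utils::write.table(out, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  js <- file.path(dir, "rule_summary.json")
  jsonlite::write_json(
    list(metadata = list(seed = seed, deviation_method = deviation_method,
                         generated = as.character(Sys.time())),
         rules = out),
    js, auto_unbox = TRUE, digits = I(10), dataframe = "rows", na = "null")
  invisible(c(tsv = tsv, json = js))
}

#' Read a reference neighbor distribution from a two-column table
#'
#' @param path TSV/whitespace-delimited file with columns `n` and
#'   `fraction` (header optional).
#' @return A tibble with `n`, `fraction` normalized to sum to 1.
#' @export
read_reference_distribution <- function(path) {
  df <- utils::read.table(path, header = TRUE)
  if (!all(c("n", "fraction") %in% names(df))) {
    df <- utils::read.table(path, header = FALSE, col.names = c("n", "fraction"))
  }
  if (any(df$fraction < 0) || sum(df$fraction) <= 0) {
    stop("reference distribution must have non-negative fractions", call. = FALSE)
  }
  tibble::tibble(n = as.integer(df$n), fraction = df$fraction / sum(df$fraction))
}
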