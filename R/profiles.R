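#' Construct a replicate time-series profile
#'
#' A `ts_profile` holds the replicated time course of one entity (a
#' metabolite, a gene, or a culture metric such as cell number) under one
#' culture condition. Metabolite and culture-metric profiles are typically
#' sampled daily over days 0--5, gene expression (FPKM) over days 0--3;
#' mixed grids are allowed and reconciled later by grid intersection.
#'
#' @param entity_id Entity name, e.g. `"PYR"`, `"Ldha"`, `"cell_number"`.
#' @param entity_kind One of `"metabolite"`, `"gene"`, `"culture_metric"`.
#' @param condition Condition label, e.g. `"0mM"`.
#' @param times Strictly increasing numeric vector of day indices (>= 0).
#' @param replicates List of numeric vectors, one per time point, each with
#'   at least one finite measurement.
#' @param units Measurement units (`"uM"`, `"FPKM"`, `"mM"`, `"cells"`, ...).
#' @return An object of class `ts_profile`.
#' @export
ts_profile <- function(entity_id, entity_kind, condition, times, replicates,
                       units) {
  stopifnot(is.character(entity_id), length(entity_id) == 1L, nzchar(entity_id))
  entity_kind <- match.arg(entity_kind,
                           c("metabolite", "gene", "culture_metric"))
  stopifnot(is.character(condition), length(condition) == 1L)
  times <- as.numeric(times)
  if (length(times) < 1L || anyNA(times) || any(times < 0))
    stop("'times' must be non-negative numbers", call. = FALSE)
  if (is.unsorted(times, strictly = TRUE))
    stop("'times' must be strictly increasing", call. = FALSE)
  if (!is.list(replicates) || length(replicates) != length(times))
    stop("'replicates' must be a list with one vector per time point",
         call. = FALSE)
  replicates <- lapply(replicates, as.numeric)
  if (any(vapply(replicates, length, 1L) < 1L))
    stop("every time point needs at least one replicate value", call. = FALSE)
  if (!all(vapply(replicates, function(v) all(is.finite(v)), TRUE)))
    stop("all replicate values must be finite", call. = FALSE)
  structure(
    list(entity_id = entity_id, entity_kind = entity_kind,
         condition = condition, times = times, replicates = replicates,
         units = units),
    class = "ts_profile")
}

#' @export
print.ts_profile <- function(x, ...) {
  cat(sprintf("<ts_profile> %s [%s] condition %s: %d time points, %s reps, %s\n",
              x$entity_id, x$entity_kind, x$condition, length(x$times),
              paste(range(vapply(x$replicates, length, 1L)), collapse = "-"),
              x$units))
  invisible(x)
}

profile_key <- function(entity_id, condition) paste(entity_id, condition,
                                                    sep = "\r")

#' Bundle profiles into a dataset
#'
#' @param profiles List of [ts_profile] objects. Keys `(entity_id, condition)`
#'   must be unique; all profiles of an entity must agree in kind and units.
#' @param metadata Optional free-form named list.
#' @return An object of class `omics_dataset`.
#' @export
profile_dataset <- function(profiles = list(), metadata = list()) {
  stopifnot(is.list(profiles))
  for (p in profiles)
    if (!inherits(p, "ts_profile"))
      stop("all elements of 'profiles' must be ts_profile objects",
           call. = FALSE)
  keys <- vapply(profiles, function(p) profile_key(p$entity_id, p$condition),
                 "")
  if (anyDuplicated(keys)) {
    dup <- profiles[[which(duplicated(keys))[1L]]]
    stop(sprintf("duplicate profile for entity '%s' under condition '%s'",
                 dup$entity_id, dup$condition), call. = FALSE)
  }
  ids <- vapply(profiles, `[[`, "", "entity_id")
  for (id in unique(ids)) {
    sub <- profiles[ids == id]
    if (length(unique(vapply(sub, `[[`, "", "entity_kind"))) > 1L)
      stop(sprintf("entity '%s' has inconsistent entity_kind across conditions",
                   id), call. = FALSE)
    if (length(unique(vapply(sub, `[[`, "", "units"))) > 1L)
      stop(sprintf("entity '%s' has inconsistent units across conditions", id),
           call. = FALSE)
  }
  names(profiles) <- keys
  structure(list(profiles = profiles, metadata = metadata),
            class = "omics_dataset")
}

#' @export
print.omics_dataset <- function(x, ...) {
  kinds <- table(vapply(x$profiles, `[[`, "", "entity_kind"))
  cat(sprintf("<omics_dataset> %d profiles (%s), conditions: %s\n",
              length(x$profiles),
              paste(names(kinds), kinds, sep = "=", collapse = ", "),
              paste(dataset_conditions(x), collapse = ", ")))
  invisible(x)
}

#' @export
length.omics_dataset <- function(x) length(x$profiles)

#' List the condition labels present in a dataset
#' @param d An `omics_dataset`.
#' @return Character vector of unique condition labels, sorted.
#' @export
dataset_conditions <- function(d) {
  sort(unique(vapply(d$profiles, `[[`, "", "condition")))
}

#' List entity ids in a dataset, optionally filtered by kind
#' @param d An `omics_dataset`.
#' @param kind Optional entity kind filter.
#' @param condition Optional condition filter.
#' @return Sorted character vector of entity ids.
#' @export
dataset_entities <- function(d, kind = NULL, condition = NULL) {
  keep <- rep(TRUE, length(d$profiles))
  if (!is.null(kind))
    keep <- keep & vapply(d$profiles, `[[`, "", "entity_kind") %in% kind
  if (!is.null(condition))
    keep <- keep & vapply(d$profiles, `[[`, "", "condition") %in% condition
  sort(unique(vapply(d$profiles[keep], `[[`, "", "entity_id")))
}

#' Retrieve one profile from a dataset
#' @param d An `omics_dataset`.
#' @param entity_id Entity name.
#' @param condition Condition label.
#' @return The matching [ts_profile].
#' @export
get_profile <- function(d, entity_id, condition) {
  p <- d$profiles[[profile_key(entity_id, condition)]]
  if (is.null(p))
    stop(sprintf("no profile for entity '%s' under condition '%s'",
                 entity_id, condition), call. = FALSE)
  p
}

#' Per-time replicate means and standard deviations
#'
#' Experimental designs here report the average of replicate (typically
#' triplicate) measurements at each time point; all downstream correlation
#' and classification operates on these means.
#'
#' @param p A [ts_profile].
#' @return A data.frame with columns `time`, `mean`, `sd` (`sd` is 0 for a
#'   single replicate).
#' @export
mean_profile <- function(p) {
  stopifnot(inherits(p, "ts_profile"))
  m <- vapply(p$replicates, mean, 0)
  s <- vapply(p$replicates, function(v) if (length(v) > 1L) stats::sd(v) else 0,
              0)
  data.frame(time = p$times, mean = m, sd = s)
}

default_profile_schema <- function() {
  c(entity_id = "entity_id", entity_kind = "entity_type",
    condition = "condition", time = "time_day", replicate = "replicate",
    value = "value", units = "units")
}

#' Read tidy long-format profiles from CSV
#'
#' Expects one measurement per row. The default column names are
#' `entity_id, entity_type, condition, time_day, replicate, value, units`;
#' `schema` remaps them. A missing observation is encoded by omitting its
#' row; empty value cells are rejected.
#'
#' @param path CSV file path.
#' @param schema Named character vector mapping the roles
#'   `entity_id, entity_kind, condition, time, replicate, value, units`
#'   to column names in the file.
#' @return An [profile_dataset()] with one profile per (entity, condition).
#' @export
read_profiles <- function(path, schema = default_profile_schema()) {
  if (!file.exists(path))
    stop(sprintf("file not found: %s", path), call. = FALSE)
  base <- default_profile_schema()
  base[names(schema)] <- schema
  schema <- base
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  missing_cols <- setdiff(unname(schema), names(df))
  if (length(missing_cols))
    stop(sprintf("schema error: missing column(s): %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  if (nrow(df) == 0L) return(profile_dataset())
  num <- function(role) {
    raw <- df[[schema[[role]]]]
    v <- suppressWarnings(as.numeric(raw))
    bad <- which(is.na(v) | !is.finite(v))
    if (length(bad))
      stop(sprintf("parse error: non-numeric %s '%s' at data row %d",
                   role, raw[bad[1L]], bad[1L]), call. = FALSE)
    v
  }
  tab <- data.frame(
    entity_id = df[[schema[["entity_id"]]]],
    entity_kind = df[[schema[["entity_kind"]]]],
    condition = df[[schema[["condition"]]]],
    time = num("time"),
    replicate = df[[schema[["replicate"]]]],
    value = num("value"),
    units = df[[schema[["units"]]]],
    stringsAsFactors = FALSE)
  dupkey <- paste(tab$entity_id, tab$condition, tab$time, tab$replicate,
                  sep = "\r")
  if (anyDuplicated(dupkey)) {
    i <- which(duplicated(dupkey))[1L]
    stop(sprintf(paste0("integrity error: duplicate measurement for entity ",
                        "'%s', condition '%s', time %g, replicate '%s'"),
                 tab$entity_id[i], tab$condition[i], tab$time[i],
                 tab$replicate[i]), call. = FALSE)
  }
  profiles <- list()
  for (key in unique(paste(tab$entity_id, tab$condition, sep = "\r"))) {
    parts <- strsplit(key, "\r", fixed = TRUE)[[1L]]
    sub <- tab[tab$entity_id == parts[1L] & tab$condition == parts[2L], ,
               drop = FALSE]
    times <- sort(unique(sub$time))
    reps <- lapply(times, function(t) {
      s <- sub[sub$time == t, , drop = FALSE]
      s$value[order(s$replicate)]
    })
    profiles[[length(profiles) + 1L]] <- ts_profile(
      entity_id = parts[1L], entity_kind = sub$entity_kind[1L],
      condition = parts[2L], times = times, replicates = reps,
      units = sub$units[1L])
  }
  profile_dataset(profiles)
}

#' Write a dataset as tidy long-format CSV
#'
#' Rows are emitted in a deterministic order (entity, condition, time,
#' replicate index) so that identical datasets produce byte-identical files.
#' `read_profiles()` on the output reproduces the dataset.
#'
#' @param d An `omics_dataset`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(d, path) {
  stopifnot(inherits(d, "omics_dataset"))
  rows <- list()
  keys <- names(d$profiles)
  ord <- order(vapply(d$profiles, `[[`, "", "entity_id"),
               vapply(d$profiles, `[[`, "", "condition"))
  for (p in d$profiles[ord]) {
    for (i in seq_along(p$times)) {
      v <- p$replicates[[i]]
      rows[[length(rows) + 1L]] <- data.frame(
        entity_id = p$entity_id, entity_type = p$entity_kind,
        condition = p$condition, time_day = p$times[i],
        replicate = seq_along(v), value = v, units = p$units,
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(entity_id = character(), entity_type = character(),
               condition = character(), time_day = numeric(),
               replicate = integer(), value = numeric(), units = character())
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  # format() keeps full double precision so round trips hold to < 1e-9
  out$value <- format(out$value, digits = 17, scientific = FALSE, trim = TRUE)
  out$time_day <- format(out$time_day, digits = 17, trim = TRUE)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
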