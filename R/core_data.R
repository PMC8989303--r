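#' Construct a patient-level feature table
#'
#' A feature table holds one row per patient, a declared kind
#' (`"numeric"` or `"categorical"`) for every predictor column, and an
#' optional binary outcome (0 = not improved, 1 = improved). Missing
#' predictor values are allowed; imputation is a blueprint-level concern.
#'
#' @param predictors data.frame of predictor columns (no id, no target).
#' @param target integer vector of 0/1 outcomes, or `NULL` for unlabeled
#'   tables. Must be non-missing when supplied.
#' @param kinds named character vector mapping every predictor column to
#'   `"numeric"` or `"categorical"`. Columns not named are inferred:
#'   numeric-typed columns become `"numeric"`, everything else
#'   `"categorical"`.
#' @param patient_id character vector of unique patient identifiers.
#' @return An object of class `feature_table`.
#' @export
feature_table <- function(predictors, target = NULL, kinds = NULL,
                          patient_id = NULL) {
  stopifnot(is.data.frame(predictors))
  n <- nrow(predictors)
  if (is.null(patient_id)) patient_id <- sprintf("P%04d", seq_len(n))
  patient_id <- as.character(patient_id)
  if (anyDuplicated(patient_id)) stop("patient ids must be unique")
  if (length(patient_id) != n) stop("patient_id length mismatch")

  full_kinds <- vapply(predictors, function(col) {
    if (is.numeric(col)) "numeric" else "categorical"
  }, character(1))
  if (!is.null(kinds)) {
    unknown <- setdiff(names(kinds), names(predictors))
    if (length(unknown)) {
      stop("unknown declared column(s): ", paste(unknown, collapse = ", "))
    }
    bad <- !kinds %in% c("numeric", "categorical")
    if (any(bad)) stop("kinds must be 'numeric' or 'categorical'")
    full_kinds[names(kinds)] <- unname(kinds)
  }
  for (nm in names(predictors)) {
    if (full_kinds[[nm]] == "numeric") {
      v <- predictors[[nm]]
      if (!is.numeric(v)) {
        suppressWarnings(vn <- as.numeric(as.character(v)))
        if (any(is.na(vn) & !is.na(v) & as.character(v) != "")) {
          stop("column '", nm, "' declared numeric but not parseable")
        }
        predictors[[nm]] <- vn
      }
    } else {
      predictors[[nm]] <- as.character(predictors[[nm]])
      predictors[[nm]][predictors[[nm]] %in% ""] <- NA_character_
    }
  }
  if (!is.null(target)) {
    if (length(target) != n) stop("target length mismatch")
    if (anyNA(target)) stop("target must be non-missing")
    tv <- unique(target)
    if (!all(tv %in% c(0, 1))) stop("non-binary target")
    target <- as.integer(target)
  }
  structure(
    list(patient_id = patient_id, predictors = predictors,
         kinds = full_kinds, target = target),
    class = "feature_table"
  )
}

#' @exportS3Method base::print
print.feature_table <- function(x, ...) {
  cat(sprintf("<feature_table> %d patients x %d predictors (%d numeric, %d categorical)\n",
              nrow(x$predictors), ncol(x$predictors),
              sum(x$kinds == "numeric"), sum(x$kinds == "categorical")))
  if (!is.null(x$target)) {
    cat(sprintf("  target: %d improved / %d not (prevalence %.3f)\n",
                sum(x$target == 1), sum(x$target == 0), mean(x$target)))
  }
  invisible(x)
}

#' @export
dim.feature_table <- function(x) dim(x$predictors)

#' Names of predictor columns
#' @param table a `feature_table`.
#' @return character vector of predictor names.
#' @export
ft_features <- function(table) names(table$predictors)

#' Load a feature table from CSV plus a schema declaration
#'
#' The schema declares the target column, the patient-id column, and the
#' kind of each predictor. It may be given as an R list or as a path to a
#' JSON sidecar with fields `target`, `id` and `kinds`.
#'
#' @param path CSV file, header row, one row per patient.
#' @param schema list with elements `target` (column name, optional),
#'   `id` (column name, optional) and `kinds` (named list/vector of
#'   `"numeric"`/`"categorical"`), or a path to an equivalent JSON file.
#' @return A [feature_table()].
#' @export
load_feature_table <- function(path, schema = list()) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.character(schema) && length(schema) == 1) {
    schema <- jsonlite::read_json(schema, simplifyVector = TRUE)
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  tcol <- schema$target
  icol <- schema$id
  kinds <- unlist(schema$kinds)
  declared <- c(tcol, icol, names(kinds))
  missing_cols <- setdiff(declared, names(df))
  if (length(missing_cols)) {
    stop("unknown declared column(s): ", paste(missing_cols, collapse = ", "))
  }
  target <- NULL
  if (!is.null(tcol)) {
    target <- df[[tcol]]
    if (!all(unique(target) %in% c(0, 1))) stop("non-binary target")
    df[[tcol]] <- NULL
  }
  pid <- NULL
  if (!is.null(icol)) {
    pid <- df[[icol]]
    df[[icol]] <- NULL
  }
  feature_table(df, target = target, kinds = kinds, patient_id = pid)
}

#' Write a feature table (and its schema sidecar) to disk
#'
#' @param table a `feature_table`.
#' @param path output CSV path.
#' @param schema_path optional JSON sidecar path recording column kinds,
#'   the id column and the target column so the table round-trips through
#'   [load_feature_table()].
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(table, path, schema_path = NULL) {
  df <- cbind(patient_id = table$patient_id, table$predictors)
  if (!is.null(table$target)) df$AIS_is_improved <- table$target
  utils::write.csv(df, path, row.names = FALSE)
  if (!is.null(schema_path)) {
    jsonlite::write_json(
      list(id = "patient_id",
           target = if (is.null(table$target)) NULL else "AIS_is_improved",
           kinds = as.list(table$kinds)),
      schema_path, auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(path)
}

#' Derive the binary improvement target from AIS grades
#'
#' The ASIA Impairment Scale is ordinal with A (complete injury) worst and
#' E (normal) best. A patient improved (target 1) iff the discharge grade
#' is strictly better than the admission grade.
#'
#' @param ais_admission,ais_discharge character vectors of grades in
#'   `A`-`E`.
#' @return integer vector of 0/1.
#' @export
derive_target <- function(ais_admission, ais_discharge) {
  grades <- c("A", "B", "C", "D", "E")
  a <- match(as.character(ais_admission), grades)
  d <- match(as.character(ais_discharge), grades)
  if (anyNA(a) || anyNA(d)) stop("unknown AIS grade symbol")
  as.integer(d > a)
}

#' Build one grouped, stratified k-fold partition plan
#'
#' Folds are stratified by the binary target and group-respecting: all
#' records of a group are assigned to the same fold (the behavior that
#' record duplication plus grouped partitioning emulates on platforms
#' with minimum-sample constraints). Every fold receives at least one
#' group of each target class, which requires each class to be present
#' in at least `k` groups.
#'
#' @param table a `feature_table` with a target.
#' @param k number of folds (>= 2).
#' @param seed integer seed; the assignment is deterministic given
#'   `(table, k, seed)`.
#' @param groups optional named vector mapping patient id to a group id;
#'   defaults to one group per patient.
#' @param duplicate if `TRUE`, each patient is duplicated and the copies
#'   grouped together (matching platform minimum-row workarounds).
#'   Default `FALSE`.
#' @return A `partition_plan`: list with `seed`, `k`, `assignment`
#'   (group -> fold, 1-based) and `fold_of` (per-patient fold).
#' @export
make_partition_plan <- function(table, k, seed, groups = NULL,
                                duplicate = FALSE) {
  stopifnot(inherits(table, "feature_table"))
  if (is.null(table$target)) stop("partitioning requires a target")
  if (k < 2) stop("k must be >= 2")
  ids <- table$patient_id
  if (duplicate) {
    # duplication only adds a same-fold copy of each record; with native
    # grouping the assignment is unchanged, so it is purely cosmetic here
    groups <- groups %||% stats::setNames(ids, ids)
  }
  if (is.null(groups)) groups <- stats::setNames(ids, ids)
  if (!all(ids %in% names(groups))) stop("groups must cover every patient")
  grp <- as.character(groups[ids])

  # class of a group = majority class of its members (first on ties)
  gids <- unique(grp)
  gclass <- vapply(gids, function(g) {
    tg <- table$target[grp == g]
    if (sum(tg == 1) > sum(tg == 0)) 1L else if (sum(tg == 0) > sum(tg == 1)) 0L else tg[1]
  }, integer(1))
  for (cl in c(0L, 1L)) {
    if (sum(gclass == cl) < k) {
      stop("class ", cl, " present in fewer than k groups; ",
           "cannot guarantee per-fold class representation")
    }
  }
  assignment <- stats::setNames(integer(length(gids)), gids)
  .with_seed(seed, {
    for (cl in c(0L, 1L)) {
      g_cl <- gids[gclass == cl]
      g_cl <- g_cl[sample.int(length(g_cl))]
      fold_order <- sample.int(k)
      assignment[g_cl] <- fold_order[((seq_along(g_cl) - 1L) %% k) + 1L]
    }
  })
  fold_of <- unname(assignment[grp])
  structure(
    list(seed = as.integer(seed), k = as.integer(k),
         assignment = assignment, fold_of = fold_of,
         patient_id = ids),
    class = "partition_plan"
  )
}

#' @exportS3Method base::print
print.partition_plan <- function(x, ...) {
  cat(sprintf("<partition_plan> k=%d seed=%d, %d records\n",
              x$k, x$seed, length(x$fold_of)))
  invisible(x)
}

#' Export a partition plan as JSON for audit
#' @param plan a `partition_plan`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_partition_plan <- function(plan, path) {
  jsonlite::write_json(
    list(seed = plan$seed, k = plan$k, assignment = as.list(plan$assignment)),
    path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Build a set of repeated cross-validation projects
#'
#' Each project is one partitioning arrangement of the same records under
#' a distinct derived seed; repeated-CV analyses aggregate over the set.
#'
#' @inheritParams make_partition_plan
#' @param n_projects number of projects (e.g. 25 for the primary
#'   workflow, 150 for sampling analyses).
#' @param master_seed integer; project seeds are drawn without
#'   replacement from a stream determined by this value, so the whole
#'   set is reproducible and seeds are pairwise distinct.
#' @return A `project_set`: list with `plans`, `k`, `master_seed`.
#' @export
make_project_set <- function(table, k, n_projects, master_seed,
                             groups = NULL) {
  if (n_projects < 1) stop("n_projects must be >= 1")
  seeds <- .with_seed(master_seed,
                      sample.int(2147483646L, n_projects, replace = FALSE))
  plans <- lapply(seeds, function(s) make_partition_plan(table, k, s, groups))
  structure(list(plans = plans, k = as.integer(k),
                 master_seed = as.integer(master_seed)),
            class = "project_set")
}

#' @exportS3Method base::print
print.project_set <- function(x, ...) {
  cat(sprintf("<project_set> %d projects, k=%d, master_seed=%d\n",
              length(x$plans), x$k, x$master_seed))
  invisible(x)
}
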