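#' Read pedigree and exam tables
#'
#' Reads a tab-delimited pedigree table (`individual_id`, `father_id`,
#' `mother_id`, `sex`, `cohort`) and a tab-delimited longitudinal exam table
#' (`individual_id`, `exam_index`, `age`, `value`, `on_lipid_meds`), validates
#' referential integrity and pedigree acyclicity, and returns a cohort object.
#' Missing parents are encoded as empty fields or `NA`; sex is `F`/`M`;
#' `on_lipid_meds` is `0`/`1` or `TRUE`/`FALSE`. Unknown columns are ignored
#' with a warning.
#'
#' @param pedigree_path path to the pedigree TSV.
#' @param exam_path path to the exam TSV.
#' @return an object of class `qh_cohort`: a list with data frames
#'   `individuals` and `exams`.
#' @export
read_cohort <- function(pedigree_path, exam_path) {
  for (p in c(pedigree_path, exam_path)) {
    if (!file.exists(p)) stop("file not found: ", p)
  }
  ped <- read.delim(pedigree_path, stringsAsFactors = FALSE,
                    na.strings = c("", "NA"), colClasses = "character")
  exm <- read.delim(exam_path, stringsAsFactors = FALSE,
                    na.strings = c("", "NA"))
  need_ped <- c("individual_id", "father_id", "mother_id", "sex", "cohort")
  need_exm <- c("individual_id", "exam_index", "age", "value", "on_lipid_meds")
  miss <- setdiff(need_ped, names(ped))
  if (length(miss)) stop("pedigree table is missing column(s): ",
                         paste(miss, collapse = ", "))
  miss <- setdiff(need_exm, names(exm))
  if (length(miss)) stop("exam table is missing column(s): ",
                         paste(miss, collapse = ", "))
  extra <- c(setdiff(names(ped), need_ped), setdiff(names(exm), need_exm))
  if (length(extra)) warning("ignoring unknown column(s): ",
                             paste(unique(extra), collapse = ", "))
  ped <- ped[need_ped]
  exm <- exm[need_exm]
  exm$individual_id <- as.character(exm$individual_id)
  exm$exam_index <- as.integer(exm$exam_index)
  exm$age <- as.numeric(exm$age)
  exm$value <- as.numeric(exm$value)
  exm$on_lipid_meds <- as.logical(exm$on_lipid_meds) |
    (suppressWarnings(as.numeric(exm$on_lipid_meds)) %in% 1)
  new_cohort(ped, exm)
}

# construct + validate a qh_cohort from in-memory tables
new_cohort <- function(individuals, exams) {
  x <- structure(list(individuals = individuals, exams = exams),
                 class = "qh_cohort")
  validate_cohort(x)
  x
}

validate_cohort <- function(x) {
  ind <- x$individuals
  exm <- x$exams
  if (anyDuplicated(ind$individual_id))
    stop("duplicated individual ids: ",
         paste(unique(ind$individual_id[duplicated(ind$individual_id)]),
               collapse = ", "))
  for (col in c("father_id", "mother_id")) {
    dangling <- setdiff(ind[[col]][!is.na(ind[[col]])], ind$individual_id)
    if (length(dangling))
      stop("dangling ", col, " value(s): ", paste(dangling, collapse = ", "))
  }
  bad <- setdiff(exm$individual_id, ind$individual_id)
  if (length(bad))
    stop("exam rows reference unknown individual(s): ",
         paste(unique(bad), collapse = ", "))
  if (anyDuplicated(exm[c("individual_id", "exam_index")]))
    stop("duplicated (individual_id, exam_index) in exam table")
  if (any(!is.finite(exm$age)) || any(exm$age <= 0))
    stop("exam ages must be finite and positive")
  if (any(!is.finite(exm$value)))
    stop("exam values must be finite")
  check_acyclic(ind)
  invisible(x)
}

# parent links must be acyclic: walk father/mother edges, detect back-edges
check_acyclic <- function(ind) {
  id <- ind$individual_id
  fa <- match(ind$father_id, id)
  mo <- match(ind$mother_id, id)
  state <- integer(length(id))  # 0 unseen, 1 on stack, 2 done
  for (start in seq_along(id)) {
    if (state[start] != 0L) next
    stack <- start
    while (length(stack)) {
      v <- stack[length(stack)]
      if (state[v] == 0L) {
        state[v] <- 1L
        for (p in c(fa[v], mo[v])) {
          if (is.na(p)) next
          if (state[p] == 1L)
            stop("pedigree cycle involving individual ", id[p])
          if (state[p] == 0L) stack <- c(stack, p)
        }
      } else {
        state[v] <- 2L
        stack <- stack[-length(stack)]
      }
    }
  }
  invisible(TRUE)
}

#' Apply the eligibility filter
#'
#' Removes exam records below the minimum age and, by default, exam records
#' taken while on lipid-lowering medication; individuals left without exams
#' are dropped. With `medication_rule = "subject"` any medicated exam
#' excludes the individual entirely.
#'
#' @param cohort a `qh_cohort`.
#' @param min_age minimum age in years (default 16).
#' @param medication_rule `"exam"` drops only the medicated exam records;
#'   `"subject"` drops every record of an individual with any medicated exam.
#' @return the filtered `qh_cohort`.
#' @export
apply_eligibility <- function(cohort, min_age = 16,
                              medication_rule = c("exam", "subject")) {
  medication_rule <- match.arg(medication_rule)
  exm <- cohort$exams
  n0 <- nrow(exm)
  if (medication_rule == "subject") {
    medicated <- unique(exm$individual_id[exm$on_lipid_meds])
    exm <- exm[!(exm$individual_id %in% medicated), , drop = FALSE]
  } else {
    exm <- exm[!exm$on_lipid_meds, , drop = FALSE]
  }
  exm <- exm[exm$age >= min_age, , drop = FALSE]
  if (nrow(exm) == 0L) stop("no eligible subjects after filtering")
  keep <- cohort$individuals$individual_id %in% exm$individual_id
  n_ind0 <- nrow(cohort$individuals)
  out <- cohort
  out$exams <- exm
  # individuals without exams are retained only as pedigree links (parents);
  # individuals that appear nowhere are dropped
  linked <- unique(c(exm$individual_id,
                     cohort$individuals$father_id[keep],
                     cohort$individuals$mother_id[keep]))
  out$individuals <- cohort$individuals[
    cohort$individuals$individual_id %in% linked, , drop = FALSE]
  message(sprintf(
    "eligibility: dropped %d of %d exam records, %d of %d individuals",
    n0 - nrow(exm), n0, n_ind0 - nrow(out$individuals), n_ind0))
  out
}

#' Write result tables of a pipeline run
#'
#' Writes per-quantile slopes, the heritability curve, trend tests and a
#' machine-readable run summary to a directory as delimited text / JSON with
#' a deterministic column order.
#'
#' @param tables named list with any of `slopes`, `h2_curve`, `table1`
#'   (data frames) and `trend_tests`, `run_summary` (lists, written as JSON).
#' @param out_dir output directory, created if absent.
#' @return invisibly, the paths written.
#' @export
write_results <- function(tables, out_dir) {
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create output directory: ", out_dir)
  }
  paths <- character(0)
  for (nm in c("slopes", "h2_curve", "table1")) {
    if (is.null(tables[[nm]])) next
    p <- file.path(out_dir, paste0(nm, ".csv"))
    write.table(tables[[nm]], p, sep = ",", row.names = FALSE, quote = FALSE)
    paths <- c(paths, p)
  }
  for (nm in c("trend_tests", "run_summary")) {
    if (is.null(tables[[nm]])) next
    p <- file.path(out_dir, paste0(nm, ".json"))
    jsonlite::write_json(tables[[nm]], p, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    paths <- c(paths, p)
  }
  invisible(paths)
}

#' Write a cohort as pedigree/exam TSV files
#'
#' Emits the same dialect consumed by [read_cohort()].
#'
#' @param cohort a `qh_cohort`.
#' @param pedigree_path,exam_path output paths.
#' @return invisibly, the two paths.
#' @export
write_cohort <- function(cohort, pedigree_path, exam_path) {
  write.table(cohort$individuals, pedigree_path, sep = "\t",
              row.names = FALSE, quote = FALSE, na = "")
  write.table(cohort$exams, exam_path, sep = "\t",
              row.names = FALSE, quote = FALSE, na = "")
  invisible(c(pedigree_path, exam_path))
}

#' @export
print.qh_cohort <- function(x, ...) {
  cat(sprintf("<qh_cohort> %d individuals (%s), %d exam records\n",
              nrow(x$individuals),
              paste(sprintf("%s: %d", names(table(x$individuals$cohort)),
                            table(x$individuals$cohort)), collapse = ", "),
              nrow(x$exams)))
  invisible(x)
}
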