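#' Construct a validated joint-model dataset
#'
#' Bundles a long-format longitudinal table and a one-row-per-subject
#' survival table into a \code{jm_data} object, enforcing the structural
#' invariants shared by all modelling stages: every subject appears in both
#' tables, every subject has at least one biomarker measurement, measurement
#' times are non-negative and never exceed the subject's event time, and
#' event codes are one of 0 (censored), 1 (death), 2 (transfer to
#' haemodialysis), 3 (kidney transplantation).
#'
#' @param longitudinal data.frame with columns \code{subject_id},
#'   \code{time} (years since dialysis start) and \code{value} (biomarker,
#'   g/L).
#' @param survival data.frame with columns \code{subject_id},
#'   \code{event_time} (years, > 0), \code{event_code} (0/1/2/3) and any
#'   number of baseline covariate columns.
#' @return An object of class \code{jm_data}: a list with elements
#'   \code{longitudinal} (sorted by subject and time), \code{survival} and
#'   \code{covariate_names}.
#' @export
jm_data <- function(longitudinal, survival) {
  need_l <- c("subject_id", "time", "value")
  need_s <- c("subject_id", "event_time", "event_code")
  miss_l <- setdiff(need_l, names(longitudinal))
  miss_s <- setdiff(need_s, names(survival))
  if (length(miss_l))
    stop("longitudinal table is missing columns: ", paste(miss_l, collapse = ", "))
  if (length(miss_s))
    stop("survival table is missing columns: ", paste(miss_s, collapse = ", "))

  longitudinal$subject_id <- as.character(longitudinal$subject_id)
  survival$subject_id <- as.character(survival$subject_id)

  for (cl in c("time", "value"))
    if (!is.numeric(longitudinal[[cl]]))
      stop("longitudinal column '", cl, "' must be numeric")
  if (!is.numeric(survival$event_time))
    stop("survival column 'event_time' must be numeric")
  if (anyDuplicated(survival$subject_id))
    stop("duplicated subject_id in survival table")
  if (!all(is.finite(longitudinal$value)))
    stop("non-finite biomarker values")
  if (any(longitudinal$time < 0))
    stop("negative measurement times")
  if (any(survival$event_time <= 0))
    stop("event_time must be > 0")
  if (!all(survival$event_code %in% 0:3))
    stop("event_code must be in {0 censored, 1 death, 2 HD, 3 KTx}")

  ids_l <- unique(longitudinal$subject_id)
  ids_s <- survival$subject_id
  orphan_l <- setdiff(ids_l, ids_s)
  orphan_s <- setdiff(ids_s, ids_l)
  if (length(orphan_l))
    stop("subjects with measurements but no survival row: ",
         paste(orphan_l, collapse = ", "))
  if (length(orphan_s))
    stop("subjects with no biomarker measurement: ",
         paste(orphan_s, collapse = ", "))

  et <- survival$event_time[match(longitudinal$subject_id, ids_s)]
  late <- longitudinal$time > et
  if (any(late))
    stop("measurements after event_time for subject(s): ",
         paste(unique(longitudinal$subject_id[late]), collapse = ", "))

  cov_names <- setdiff(names(survival), need_s)
  for (cl in cov_names) {
    if (!is.numeric(survival[[cl]]))
      stop("covariate column '", cl, "' must be numeric")
    if (anyNA(survival[[cl]]))
      stop("missing values in covariate '", cl, "' (imputation not supported)")
  }

  o <- order(longitudinal$subject_id, longitudinal$time)
  longitudinal <- longitudinal[o, need_l, drop = FALSE]
  rownames(longitudinal) <- NULL
  survival <- survival[order(survival$subject_id), , drop = FALSE]
  rownames(survival) <- NULL

  structure(list(longitudinal = longitudinal,
                 survival = survival,
                 covariate_names = cov_names),
            class = "jm_data")
}

#' @export
print.jm_data <- function(x, ...) {
  n <- nrow(x$survival)
  tab <- table(factor(x$survival$event_code, levels = 0:3))
  cat("Joint-model dataset: ", n, " subjects, ",
      nrow(x$longitudinal), " biomarker measurements\n", sep = "")
  cat("  events: ", tab[2], " death, ", tab[3], " transfer-to-HD, ",
      tab[4], " transplant, ", tab[1], " censored\n", sep = "")
  if (length(x$covariate_names))
    cat("  baseline covariates:", paste(x$covariate_names, collapse = ", "), "\n")
  invisible(x)
}

#' Number of subjects in a jm_data object
#' @param data a \code{jm_data} object
#' @export
n_subjects <- function(data) nrow(data$survival)

#' Read a joint-model dataset from two CSV files
#'
#' @param longitudinal_path CSV with header \code{subject_id,time,value}.
#' @param survival_path CSV with header
#'   \code{subject_id,event_time,event_code,<covariate...>}.
#' @return A validated \code{jm_data} object.
#' @seealso [write_jm_data()] for the inverse operation.
#' @export
read_jm_data <- function(longitudinal_path, survival_path) {
  long <- utils::read.csv(longitudinal_path, stringsAsFactors = FALSE)
  surv <- utils::read.csv(survival_path, stringsAsFactors = FALSE)
  jm_data(long, surv)
}

#' Write a joint-model dataset to two CSV files
#'
#' @param data a \code{jm_data} object.
#' @param longitudinal_path,survival_path output CSV paths.
#' @export
write_jm_data <- function(data, longitudinal_path, survival_path) {
  stopifnot(inherits(data, "jm_data"))
  utils::write.csv(data$longitudinal, longitudinal_path, row.names = FALSE)
  utils::write.csv(data$survival, survival_path, row.names = FALSE)
  invisible(data)
}

#' Subset a jm_data object by subject ids
#' @param data a \code{jm_data} object
#' @param ids character vector of subject ids to keep
#' @export
subset_subjects <- function(data, ids) {
  stopifnot(inherits(data, "jm_data"))
  jm_data(data$longitudinal[data$longitudinal$subject_id %in% ids, , drop = FALSE],
          data$survival[data$survival$subject_id %in% ids, , drop = FALSE])
}

#' Subject-level train/test split
#'
#' Partitions the subjects of a dataset at random into a training and a
#' testing set. The training size is \code{round(ratio * N)}, which at the
#' conventional 3-to-1 ratio splits a 314-subject cohort into 236 training
#' and 78 testing subjects.
#'
#' @param data a \code{jm_data} object.
#' @param ratio training fraction, strictly between 0 and 1 (default 0.75).
#' @param seed integer seed; the partition is deterministic given the seed.
#' @return list with elements \code{train} and \code{test}, both
#'   \code{jm_data}.
#' @export
split_train_test <- function(data, ratio = 0.75, seed = 1L) {
  stopifnot(inherits(data, "jm_data"))
  if (!is.numeric(ratio) || length(ratio) != 1 || ratio <= 0 || ratio >= 1)
    stop("ratio must lie strictly between 0 and 1")
  ids <- data$survival$subject_id
  n <- length(ids)
  if (n == 0) stop("empty dataset")
  n_train <- round(ratio * n)
  n_train <- max(1L, min(n - 1L, as.integer(n_train)))
  perm <- local({ set.seed(as.integer(seed)); sample(ids) })
  train_ids <- perm[seq_len(n_train)]
  list(train = subset_subjects(data, train_ids),
       test  = subset_subjects(data, setdiff(ids, train_ids)))
}
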