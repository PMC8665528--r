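#' Construct a single-subgroup survival dataset
#'
#' Bundles a continuous covariate matrix with right-censored survival
#' outcomes for one patient subgroup (cohort). All model-fitting functions
#' operate on lists of these objects assembled by
#' [multi_subgroup_data()].
#'
#' @param covariates numeric matrix (patients in rows, genes in columns),
#'   no missing values; column names identify the genes.
#' @param time strictly positive observed times (event or censoring).
#' @param event event indicator, 1 = event observed, 0 = right-censored.
#' @param subgroup_id label for the subgroup.
#' @return An object of class `"subgroup_dataset"`.
#' @export
subgroup_dataset <- function(covariates, time, event, subgroup_id = "1") {
  covariates <- as.matrix(covariates)
  if (is.null(colnames(covariates)))
    colnames(covariates) <- paste0("x", seq_len(ncol(covariates)))
  n <- nrow(covariates)
  if (length(time) != n || length(event) != n)
    stop("'time' and 'event' must have one entry per row of 'covariates'")
  if (anyNA(covariates) || anyNA(time) || anyNA(event))
    stop("missing values are not allowed in subgroup '", subgroup_id, "'")
  if (any(time <= 0)) {
    bad <- which(time <= 0)
    stop("non-positive time for row(s) ", paste(bad, collapse = ", "),
         " in subgroup '", subgroup_id, "'")
  }
  if (!all(event %in% c(0, 1))) {
    bad <- which(!(event %in% c(0, 1)))
    stop("event indicator must be 0 or 1; offending row(s) ",
         paste(bad, collapse = ", "), " in subgroup '", subgroup_id, "'")
  }
  structure(list(covariates = covariates, time = as.numeric(time),
                 event = as.integer(event),
                 subgroup_id = as.character(subgroup_id)),
            class = "subgroup_dataset")
}

#' Combine subgroup datasets sharing a common gene panel
#'
#' @param subgroups list of [subgroup_dataset()] objects with identical
#'   column names in identical order and unique subgroup labels.
#' @return An object of class `"multi_subgroup_data"` with elements
#'   `subgroups` and `gene_names`.
#' @export
multi_subgroup_data <- function(subgroups) {
  if (!length(subgroups)) stop("need at least one subgroup")
  stopifnot(all(vapply(subgroups, inherits, logical(1), "subgroup_dataset")))
  genes <- colnames(subgroups[[1]]$covariates)
  for (sg in subgroups[-1]) {
    if (!identical(colnames(sg$covariates), genes))
      stop("all subgroups must share the same genes in the same order")
  }
  ids <- vapply(subgroups, `[[`, character(1), "subgroup_id")
  if (anyDuplicated(ids)) stop("subgroup labels must be unique")
  names(subgroups) <- ids
  structure(list(subgroups = subgroups, gene_names = genes),
            class = "multi_subgroup_data")
}

#' @export
print.multi_subgroup_data <- function(x, ...) {
  ns <- vapply(x$subgroups, function(s) nrow(s$covariates), integer(1))
  ev <- vapply(x$subgroups, function(s) sum(s$event), integer(1))
  cat("Multi-subgroup survival data: S =", length(x$subgroups),
      "subgroups, p =", length(x$gene_names), "genes\n")
  for (i in seq_along(ns))
    cat(sprintf("  subgroup %s: n = %d (%d events)\n",
                names(x$subgroups)[i], ns[i], ev[i]))
  invisible(x)
}

#' Read multi-subgroup survival data from delimited text files
#'
#' The survival table must contain columns `id`, `time`, `status` and
#' `subgroup`; the covariate table has `id` in its first column and one
#' gene per remaining column. Rows are matched by id. Comma or tab
#' delimiters are autodetected from the header line.
#'
#' @param survival_path,covariate_path file paths.
#' @return A [multi_subgroup_data()] object with one subgroup per distinct
#'   subgroup label (in order of first appearance).
#' @export
load_multi_subgroup <- function(survival_path, covariate_path) {
  surv <- .read_delim_auto(survival_path)
  need <- c("id", "time", "status", "subgroup")
  if (!all(need %in% names(surv)))
    stop("survival table must have columns ", paste(need, collapse = ", "))
  covs <- .read_delim_auto(covariate_path)
  if (names(covs)[1] != "id") stop("covariate table must start with an 'id' column")
  surv$id <- as.character(surv$id)
  covs$id <- as.character(covs$id)
  if (anyNA(surv) || anyNA(covs)) stop("missing values in input tables")
  missing_ids <- setdiff(surv$id, covs$id)
  if (length(missing_ids))
    stop("ids without covariate rows: ", paste(missing_ids, collapse = ", "))
  xm <- as.matrix(covs[match(surv$id, covs$id), -1, drop = FALSE])
  storage.mode(xm) <- "double"
  rownames(xm) <- surv$id
  labs <- unique(surv$subgroup)
  subgroups <- lapply(labs, function(lab) {
    rows <- surv$subgroup == lab
    if (!all(surv$status[rows] %in% c(0, 1))) {
      bad <- surv$id[rows][!(surv$status[rows] %in% c(0, 1))]
      stop("non-binary status for id(s): ", paste(bad, collapse = ", "))
    }
    if (any(surv$time[rows] <= 0)) {
      bad <- surv$id[rows][surv$time[rows] <= 0]
      stop("non-positive time for id(s): ", paste(bad, collapse = ", "))
    }
    subgroup_dataset(xm[rows, , drop = FALSE], surv$time[rows],
                     surv$status[rows], subgroup_id = lab)
  })
  multi_subgroup_data(subgroups)
}

#' Write multi-subgroup data as the two standard CSV tables
#'
#' @param data a [multi_subgroup_data()] object.
#' @param survival_path,covariate_path output file paths.
#' @export
write_multi_subgroup <- function(data, survival_path, covariate_path) {
  rows <- lapply(data$subgroups, function(sg) {
    ids <- rownames(sg$covariates)
    if (is.null(ids))
      ids <- paste0(sg$subgroup_id, "_", seq_along(sg$time))
    data.frame(id = ids, time = sg$time, status = sg$event,
               subgroup = sg$subgroup_id, stringsAsFactors = FALSE)
  })
  surv <- do.call(rbind, rows)
  xm <- do.call(rbind, lapply(data$subgroups, `[[`, "covariates"))
  covs <- data.frame(id = surv$id, xm, check.names = FALSE,
                     stringsAsFactors = FALSE)
  utils::write.csv(surv, survival_path, row.names = FALSE, quote = FALSE)
  utils::write.csv(covs, covariate_path, row.names = FALSE, quote = FALSE)
  invisible(data)
}

.read_delim_auto <- function(path) {
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                    stringsAsFactors = FALSE)
}

#' Standardize covariates to zero mean and unit variance
#'
#' Centers and scales each gene, either separately per subgroup (used by
#' the joint and subgroup models) or with pooled means and standard
#' deviations across all subgroups (used by the pooled model). The
#' returned parameters are the training-data statistics and must be reused
#' on test data via [apply_standardization()] so that test covariates are
#' expressed on the training scale.
#'
#' @param data a [multi_subgroup_data()] object.
#' @param mode `"per_subgroup"` or `"pooled"`.
#' @return list with elements `data` (standardized copy) and `params`
#'   (per-subgroup list, or a single element named `"pooled"`, each with
#'   `means` and `sds`; sample sd uses denominator n - 1).
#' @export
standardize <- function(data, mode = c("per_subgroup", "pooled")) {
  mode <- match.arg(mode)
  if (mode == "pooled") {
    xm <- do.call(rbind, lapply(data$subgroups, `[[`, "covariates"))
    par <- .scale_params(xm, data$gene_names)
    params <- list(pooled = par)
    data$subgroups <- lapply(data$subgroups, .apply_scale, par = par)
  } else {
    params <- lapply(data$subgroups, function(sg)
      .scale_params(sg$covariates, data$gene_names))
    data$subgroups <- Map(.apply_scale, data$subgroups, params)
  }
  list(data = data, params = params)
}

.scale_params <- function(xm, genes) {
  if (nrow(xm) < 2) stop("need at least 2 observations to standardize")
  means <- colMeans(xm)
  sds <- apply(xm, 2, stats::sd)
  if (any(sds <= 0)) {
    stop("zero-variance gene(s): ",
         paste(genes[sds <= 0], collapse = ", "))
  }
  list(means = means, sds = sds)
}

.apply_scale <- function(sg, par) {
  sg$covariates <- sweep(sweep(sg$covariates, 2, par$means), 2, par$sds, "/")
  sg
}

#' Apply previously estimated standardization parameters
#'
#' @param data a [multi_subgroup_data()] object (e.g. test data).
#' @param params the `params` element returned by [standardize()] on the
#'   training data.
#' @return the data on the training scale.
#' @export
apply_standardization <- function(data, params) {
  if (identical(names(params), "pooled")) {
    data$subgroups <- lapply(data$subgroups, .apply_scale,
                             par = params$pooled)
  } else {
    if (!all(names(data$subgroups) %in% names(params)))
      stop("params missing for subgroup(s): ",
           paste(setdiff(names(data$subgroups), names(params)), collapse = ", "))
    data$subgroups <- Map(function(sg, lab) .apply_scale(sg, params[[lab]]),
                          data$subgroups, names(data$subgroups))
  }
  data
}

#' Split data into training and test sets, stratified by subgroup and event
#'
#' Within every (subgroup, event-status) stratum a fixed fraction of
#' patients is sampled into the training set, so that censoring rates and
#' subgroup proportions are preserved up to rounding.
#'
#' @param data a [multi_subgroup_data()] object.
#' @param train_fraction proportion assigned to training (default 0.8).
#' @param seed integer seed; the split is deterministic given the seed.
#' @return list with elements `train` and `test`.
#' @export
stratified_split <- function(data, train_fraction = 0.8, seed = 1L) {
  stopifnot(train_fraction > 0, train_fraction <= 1)
  set.seed(seed)
  pick <- lapply(data$subgroups, function(sg) {
    idx_train <- integer(0)
    for (ev in c(0, 1)) {
      stratum <- which(sg$event == ev)
      if (length(stratum) < 2)
        stop("stratum (subgroup ", sg$subgroup_id, ", event ", ev,
             ") has fewer than 2 members")
      k <- round(train_fraction * length(stratum))
      idx_train <- c(idx_train, sort(sample(stratum, k)))
    }
    sort(idx_train)
  })
  subset_sg <- function(sg, idx) {
    subgroup_dataset(sg$covariates[idx, , drop = FALSE], sg$time[idx],
                     sg$event[idx], sg$subgroup_id)
  }
  train <- Map(function(sg, idx) subset_sg(sg, idx), data$subgroups, pick)
  test <- Map(function(sg, idx) subset_sg(sg, setdiff(seq_along(sg$time), idx)),
              data$subgroups, pick)
  if (train_fraction == 1)
    warning("train_fraction = 1: test set is empty")
  list(train = multi_subgroup_data(train),
       test = multi_subgroup_data(test))
}
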