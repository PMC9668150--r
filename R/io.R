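#' Convert a white-blood-cell concentration to a total cell count
#'
#' `cells = wbc_per_ul * blood_volume_l * 1e6` (one liter is `1e6`
#' microliters). The leukocytosis criterion of 11,500 WBC/uL in 5 L of
#' blood corresponds to `5.75e10` cells.
#'
#' @param wbc_per_ul White blood cell count per microliter (> 0).
#' @param blood_volume_l Total blood volume in liters (default 5).
#' @return Total cell count.
#' @examples
#' wbc_to_cell_count(11500)  # 5.75e10
#' @export
wbc_to_cell_count <- function(wbc_per_ul, blood_volume_l = 5) {
  if (any(wbc_per_ul <= 0) || any(blood_volume_l <= 0))
    stop("'wbc_per_ul' and 'blood_volume_l' must be positive")
  wbc_per_ul * blood_volume_l * 1e6
}

#' Assemble a patient data bundle
#'
#' Collects everything the patient-facing estimators need: the clone tree,
#' per-timepoint bulk observations (total cell count and cumulative driver
#' CCFs), subclonal mutation counts with their sequencing metadata,
#' per-clone clonal (branch) mutation counts, CCF posterior samples in the
#' style of subclonal-reconstruction output, and the WBC series.
#'
#' @param patient_id Identifier string.
#' @param parent Integer vector: parent clone of each driver `1..k`.
#' @param observations Data frame with columns `timepoint`, `age_yr`, `M`,
#'   `clone`, `cumulative_ccf` (one row per driver per timepoint).
#' @param gamma Data frame with columns `timepoint`, `gamma_obs`, `f1`,
#'   `f2`, `coverage`, `purity`, `threshold`.
#' @param m_obs Numeric vector of observed clonal counts for clones `0..k`
#'   (truncal count first).
#' @param ccf_posterior Data frame with columns `clone`, `timepoint`,
#'   `draw`, `ccf`.
#' @param wbc Data frame with columns `age_yr`, `wbc_per_ul` (may be empty
#'   if detectability is not requested).
#' @param diagnosis_age Patient age at diagnosis (years).
#' @param config Named list of constants (`blood_volume_l`,
#'   `leukocytosis_per_ul`, optional `parent_origin_ages`).
#' @return A `patient_bundle` object.
#' @export
patient_bundle <- function(patient_id, parent, observations, gamma, m_obs,
                           ccf_posterior, wbc = NULL, diagnosis_age = NA,
                           config = list()) {
  k <- length(parent)
  .check_columns(observations, c("timepoint", "age_yr", "M", "clone",
                                 "cumulative_ccf"), "observations")
  .check_columns(gamma, c("timepoint", "gamma_obs", "f1", "f2", "coverage",
                          "purity", "threshold"), "gamma")
  .check_columns(ccf_posterior, c("clone", "timepoint", "draw", "ccf"),
                 "ccf_posterior")
  bad <- which(observations$cumulative_ccf < 0 | observations$cumulative_ccf > 1)
  if (length(bad))
    stop("observations: cumulative_ccf outside [0, 1] at row ", bad[1])
  bad <- which(ccf_posterior$ccf < 0 | ccf_posterior$ccf > 1)
  if (length(bad))
    stop("ccf_posterior: ccf outside [0, 1] at row ", bad[1])
  if (any(!observations$clone %in% seq_len(k)))
    stop("observations reference a clone not in the tree")
  ages <- tapply(observations$age_yr, observations$timepoint, unique)
  if (is.unsorted(as.numeric(ages), strictly = TRUE))
    stop("timepoint ages must be strictly increasing")
  if (length(m_obs) != k + 1L)
    stop("'m_obs' must have one entry per clone (truncal count first)")
  if (!is.null(wbc) && nrow(wbc)) .check_columns(wbc, c("age_yr", "wbc_per_ul"), "wbc")
  structure(list(patient_id = patient_id, parent = as.integer(parent),
                 n_clones = k + 1L, observations = observations,
                 gamma = gamma, m_obs = m_obs,
                 ccf_posterior = ccf_posterior, wbc = wbc,
                 diagnosis_age = diagnosis_age, config = config),
            class = "patient_bundle")
}

.check_columns <- function(df, cols, what) {
  if (!is.data.frame(df)) stop("'", what, "' must be a data frame")
  miss <- setdiff(cols, names(df))
  if (length(miss))
    stop("'", what, "' is missing column(s): ", paste(miss, collapse = ", "))
  invisible(df)
}

#' Write / read a patient bundle as a directory of TSV files
#'
#' The on-disk layout is `tree.tsv` (clone, parent), `observations.tsv`,
#' `gamma.tsv`, `clonal_counts.tsv` (clone, m_obs), `ccf_posterior.tsv`,
#' `wbc.tsv` and `meta.json`. Writers produce files the reader accepts and
#' the round trip is lossless.
#'
#' @param bundle A [patient_bundle()].
#' @param dir Directory to write to / read from (created if needed).
#' @return `write_patient_bundle` returns `dir` invisibly;
#'   `read_patient_bundle` returns a `patient_bundle`.
#' @export
write_patient_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "patient_bundle"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(df, name)
    write.table(df, file.path(dir, name), sep = "\t", row.names = FALSE,
                quote = FALSE)
  k <- bundle$n_clones - 1L
  w(data.frame(clone = seq_len(k), parent = bundle$parent), "tree.tsv")
  w(bundle$observations, "observations.tsv")
  w(bundle$gamma, "gamma.tsv")
  w(data.frame(clone = 0:k, m_obs = bundle$m_obs), "clonal_counts.tsv")
  w(bundle$ccf_posterior, "ccf_posterior.tsv")
  if (!is.null(bundle$wbc)) w(bundle$wbc, "wbc.tsv")
  meta <- list(patient_id = bundle$patient_id,
               diagnosis_age = bundle$diagnosis_age,
               config = bundle$config)
  jsonlite::write_json(meta, file.path(dir, "meta.json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(dir)
}

#' @rdname write_patient_bundle
#' @export
read_patient_bundle <- function(dir) {
  rd <- function(name, required = TRUE) {
    path <- file.path(dir, name)
    if (!file.exists(path)) {
      if (required) stop("missing bundle file: ", name)
      return(NULL)
    }
    read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  }
  tree <- rd("tree.tsv")
  .check_columns(tree, c("clone", "parent"), "tree.tsv")
  meta <- jsonlite::read_json(file.path(dir, "meta.json"),
                              simplifyVector = TRUE)
  cfg <- as.list(meta$config)
  patient_bundle(
    patient_id = meta$patient_id,
    parent = tree$parent[order(tree$clone)],
    observations = rd("observations.tsv"),
    gamma = rd("gamma.tsv"),
    m_obs = {
      cc <- rd("clonal_counts.tsv")
      .check_columns(cc, c("clone", "m_obs"), "clonal_counts.tsv")
      cc$m_obs[order(cc$clone)]
    },
    ccf_posterior = rd("ccf_posterior.tsv"),
    wbc = rd("wbc.tsv", required = FALSE),
    diagnosis_age = meta$diagnosis_age %||% NA,
    config = cfg)
}
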