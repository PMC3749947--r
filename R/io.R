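# Configuration and dataset I/O.
#
# The model configuration is a YAML file with blocks `ligands`, `rates`,
# `pf`, `trafficking` and `expression`; keys carry their units
# (`_per_min`, `_per_nm_min`, ...).  Datasets are tidy CSV with one row
# per replicate measurement.

.config_version <- "1.0"

#' Write a model configuration to YAML
#'
#' @param params A [her_parameters()] object.
#' @param path Output file.
#' @param profiles Optional expression table ([her_cell_lines()] format)
#'   stored in the `expression` block.
#' @return `path`, invisibly.
#' @export
her_save_config <- function(params, path, profiles = her_cell_lines()) {
  stopifnot(inherits(params, "her_parameters"))
  b <- params$binding
  tr <- function(cl) {
    v <- params$trafficking[[cl]]
    list(kt_per_min = unname(v[["kt"]]), ke_per_min = unname(v[["ke"]]),
         kx_per_min = unname(v[["kx"]]), f = unname(v[["f"]]))
  }
  cfg <- list(
    version = .config_version,
    ligands = list(
      egf = list(mw_kda = unname(params$ligand_mw_kda[["egf"]]),
                 kon_s_per_nm_min = b$kon1s, koff_s_per_min = b$koff1s,
                 kon_e_per_nm_min = b$kon1e, koff_e_per_min = b$koff1e),
      hrg = list(mw_kda = unname(params$ligand_mw_kda[["hrg"]]),
                 kon_s_per_nm_min = b$kon3s, koff_s_per_min = b$koff3s,
                 kon_e_per_nm_min = b$kon3e, koff_e_per_min = b$koff3e)),
    rates = list(
      kc_s_per_cell_min = unname(params$kc[["s"]]),
      kc_e_per_cell_min = unname(params$kc[["e"]]),
      ee_volume_factor = params$ee_volume_factor,
      affinity_fold = as.list(params$affinity_fold),
      ku_per_min = as.list(params$ku)),
    pf = as.list(params$pf),
    trafficking = list(delta1 = params$delta1,
                       her1 = tr("her1"), her23 = tr("her23")),
    expression = if (!is.null(profiles)) {
      stats::setNames(lapply(seq_len(nrow(profiles)), function(i)
        list(her1 = profiles$her1[i], her2 = profiles$her2[i],
             her3 = profiles$her3[i])), profiles$name)
    }
  )
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' Load and validate a model configuration
#'
#' Reads a YAML configuration, validates it exhaustively (every problem
#' is collected and reported at once, not first-failure), verifies the
#' free/fixed partition (20 ku + 26 pf + delta1 = 47 free parameters) and
#' returns the assembled parameter set plus any expression profiles.
#' Loading, saving and re-loading is idempotent.
#'
#' @param path YAML file path.
#' @return A list with `params` ([her_parameters()]), `profiles`
#'   (data.frame or `NULL`) and `version`.
#' @export
her_load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  cfg <- yaml::read_yaml(path)
  errs <- character(0)
  need_block <- c("ligands", "rates", "pf", "trafficking")
  for (blk in need_block)
    if (is.null(cfg[[blk]])) errs <- c(errs, paste0("missing block: ", blk))
  lig_keys <- c("mw_kda", "kon_s_per_nm_min", "koff_s_per_min",
                "kon_e_per_nm_min", "koff_e_per_min")
  for (lg in c("egf", "hrg")) {
    for (k in lig_keys)
      if (is.null(cfg$ligands[[lg]][[k]]))
        errs <- c(errs, paste0("missing ligands$", lg, "$", k))
  }
  for (k in c("kc_s_per_cell_min", "kc_e_per_cell_min"))
    if (is.null(cfg$rates[[k]])) errs <- c(errs, paste0("missing rates$", k))
  ku <- unlist(cfg$rates$ku_per_min)
  miss_ku <- setdiff(.ku_names(), names(ku))
  if (length(miss_ku) > 0)
    errs <- c(errs, paste0("missing ku entries: ",
                           paste(miss_ku, collapse = ", ")))
  pf <- unlist(cfg$pf)
  miss_pf <- setdiff(.pf_names(), names(pf))
  if (length(miss_pf) > 0)
    errs <- c(errs, paste0("missing pf entries: ",
                           paste(miss_pf, collapse = ", ")))
  if (is.null(cfg$trafficking$delta1))
    errs <- c(errs, "missing trafficking$delta1")
  for (cl in c("her1", "her23"))
    for (k in c("kt_per_min", "ke_per_min", "kx_per_min", "f"))
      if (is.null(cfg$trafficking[[cl]][[k]]))
        errs <- c(errs, paste0("missing trafficking$", cl, "$", k))
  if (length(errs) > 0)
    stop("invalid configuration '", path, "':\n  - ",
         paste(errs, collapse = "\n  - "), call. = FALSE)

  n_free <- length(ku) + length(pf) + 1L
  if (n_free != 47L)
    stop("free/fixed partition check failed: ", n_free,
         " free parameters instead of 47", call. = FALSE)

  lg <- cfg$ligands
  params <- her_parameters(
    ku = ku[.ku_names()],
    pf = pf[.pf_names()],
    delta1 = cfg$trafficking$delta1,
    binding = list(
      kon1s = lg$egf$kon_s_per_nm_min, koff1s = lg$egf$koff_s_per_min,
      kon1e = lg$egf$kon_e_per_nm_min, koff1e = lg$egf$koff_e_per_min,
      kon3s = lg$hrg$kon_s_per_nm_min, koff3s = lg$hrg$koff_s_per_min,
      kon3e = lg$hrg$kon_e_per_nm_min, koff3e = lg$hrg$koff_e_per_min),
    kc = c(s = cfg$rates$kc_s_per_cell_min, e = cfg$rates$kc_e_per_cell_min),
    affinity_fold = unlist(cfg$rates$affinity_fold),
    trafficking = list(
      her1 = c(kt = cfg$trafficking$her1$kt_per_min,
               ke = cfg$trafficking$her1$ke_per_min,
               kx = cfg$trafficking$her1$kx_per_min,
               f = cfg$trafficking$her1$f),
      her23 = c(kt = cfg$trafficking$her23$kt_per_min,
                ke = cfg$trafficking$her23$ke_per_min,
                kx = cfg$trafficking$her23$kx_per_min,
                f = cfg$trafficking$her23$f)),
    ligand_mw_kda = c(egf = lg$egf$mw_kda, hrg = lg$hrg$mw_kda),
    ee_volume_factor = if (is.null(cfg$rates$ee_volume_factor)) 1
                       else cfg$rates$ee_volume_factor
  )
  profiles <- NULL
  if (!is.null(cfg$expression)) {
    profiles <- do.call(rbind, lapply(names(cfg$expression), function(nm) {
      e <- cfg$expression[[nm]]
      data.frame(name = nm, her1 = e$her1, her2 = e$her2, her3 = e$her3,
                 stringsAsFactors = FALSE)
    }))
  }
  list(params = params, profiles = profiles,
       version = if (is.null(cfg$version)) NA_character_ else cfg$version)
}

.dataset_columns <- c("cell_line", "egf_ng_ml", "hrg_ng_ml", "block",
                      "time_min", "measurement", "replicate", "value")

#' Write a dataset to tidy CSV
#'
#' @param dataset A `her_dataset` data.frame.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
her_write_dataset <- function(dataset, path) {
  miss <- setdiff(.dataset_columns, names(dataset))
  if (length(miss) > 0)
    stop("dataset lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  utils::write.csv(dataset[, .dataset_columns], path, row.names = FALSE)
  invisible(path)
}

#' Read and validate a dataset from tidy CSV
#'
#' @param path CSV file with the `her_dataset` schema (header required).
#' @return A `her_dataset` data.frame.
#' @export
her_read_dataset <- function(path) {
  if (!file.exists(path)) stop("dataset file not found: ", path,
                               call. = FALSE)
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  errs <- character(0)
  miss <- setdiff(.dataset_columns, names(d))
  if (length(miss) > 0)
    errs <- c(errs, paste0("missing column(s): ",
                           paste(miss, collapse = ", ")))
  if (length(errs) == 0) {
    bad <- setdiff(unique(d$measurement), .measurement_labels)
    if (length(bad) > 0)
      errs <- c(errs, paste0("unknown measurement label(s): ",
                             paste(bad, collapse = ", ")))
    if (any(!is.finite(d$value)))
      errs <- c(errs, "non-finite values present")
    else if (any(d$value < 0))
      errs <- c(errs, "negative measurement values present")
  }
  if (length(errs) > 0)
    stop("invalid dataset '", path, "':\n  - ",
         paste(errs, collapse = "\n  - "), call. = FALSE)
  class(d) <- c("her_dataset", "data.frame")
  d
}
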