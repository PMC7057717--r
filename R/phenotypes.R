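#' Build contemporary groups
#'
#' Assigns each record a contemporary-group id as the deterministic
#' concatenation of farm, birth year, birth season, sex and management
#' group.  Records missing any factor are dropped and logged.
#'
#' @param raw `data.frame` with columns `animal`, `trait`, `value`,
#'   `age_days`, `hd`, and the factor columns `farm`, `birth_year`,
#'   `season`, `sex`, `mgmt_group`.
#' @return Phenotype `data.frame` with a `cg` column; attribute
#'   `dropped` holds records removed for missing factors.
#' @export
build_contemporary_groups <- function(raw) {
  fac <- c("farm", "birth_year", "season", "sex", "mgmt_group")
  stopifnot(all(fac %in% names(raw)))
  miss <- Reduce(`|`, lapply(raw[fac], function(x) is.na(x) | x == ""))
  dropped <- raw[miss, , drop = FALSE]
  out <- raw[!miss, , drop = FALSE]
  out$cg <- do.call(paste, c(out[fac], sep = ":"))
  rownames(out) <- NULL
  attr(out, "dropped") <- dropped
  out
}

#' Remove phenotypic outliers within contemporary group
#'
#' Single pass: within each contemporary group x trait cell, records
#' deviating more than `sd_limit` standard deviations from that cell's
#' mean are removed.  Mean and SD are computed on the pre-filter records
#' of the cell; degenerate cells (SD zero or undefined) lose nothing.
#'
#' @param t Phenotype `data.frame` with `cg`, `trait`, `value`.
#' @param sd_limit Deviation threshold in SD units (default 3.5).
#' @return Filtered `data.frame`; attribute `edit_log` records removals
#'   with reason `"outlier_3p5sd"`.
#' @export
filter_outliers <- function(t, sd_limit = 3.5) {
  stopifnot(all(c("cg", "trait", "value") %in% names(t)))
  key <- interaction(t$cg, t$trait, drop = TRUE)
  mu <- stats::ave(t$value, key, FUN = mean)
  sdv <- stats::ave(t$value, key, FUN = function(v) {
    if (length(v) < 2) 0 else stats::sd(v)
  })
  out_flag <- sdv > 0 & abs(t$value - mu) > sd_limit * sdv
  log <- t[out_flag, , drop = FALSE]
  if (nrow(log)) log$reason <- "outlier_3p5sd"
  out <- t[!out_flag, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "edit_log") <- log
  out
}

#' Drop small contemporary groups
#'
#' Removes entire contemporary-group x trait cells with fewer than
#' `min_n` records (after outlier editing).
#'
#' @param t Phenotype `data.frame` with `cg`, `trait`.
#' @param min_n Minimum records per cell (default 5).
#' @return Filtered `data.frame`; attribute `edit_log` records removals
#'   with reason `"small_cg"`.
#' @export
filter_small_cgs <- function(t, min_n = 5) {
  stopifnot(all(c("cg", "trait") %in% names(t)))
  key <- interaction(t$cg, t$trait, drop = TRUE)
  n <- stats::ave(seq_len(nrow(t)), key, FUN = length)
  drop <- n < min_n
  log <- t[drop, , drop = FALSE]
  if (nrow(log)) log$reason <- "small_cg"
  out <- t[!drop, , drop = FALSE]
  if (!nrow(out)) stop("no phenotype records survive contemporary-group ",
                       "size filtering")
  rownames(out) <- NULL
  attr(out, "edit_log") <- log
  out
}

#' Full phenotype editing pipeline
#'
#' Contemporary-group assignment, 3.5-SD outlier removal within CG, then
#' exclusion of CG cells with fewer than five records — in that order.
#'
#' @inheritParams build_contemporary_groups
#' @inheritParams filter_outliers
#' @inheritParams filter_small_cgs
#' @return Cleaned phenotype `data.frame`; attribute `edit_log` combines
#'   both filters' removal records.
#' @export
edit_phenotypes <- function(raw, sd_limit = 3.5, min_n = 5) {
  t1 <- build_contemporary_groups(raw)
  t2 <- filter_outliers(t1, sd_limit = sd_limit)
  t3 <- filter_small_cgs(t2, min_n = min_n)
  log2 <- attr(t2, "edit_log"); log3 <- attr(t3, "edit_log")
  attr(t3, "edit_log") <- rbind(log2, log3)
  t3
}
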