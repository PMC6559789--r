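#' Specimens-by-regions table of counts or volumes
#'
#' A matrix of per-region nucleus counts (or region volumes in um^3) with
#' one column per specimen, the container for cross-specimen statistics.
#'
#' @param values numeric matrix or data.frame, regions in rows, specimens in
#'   columns; all entries non-negative.
#' @param regions region names (defaults to rownames).
#' @param specimens specimen ids (defaults to colnames).
#' @return object of class `region_table`.
#' @export
region_table <- function(values, regions = rownames(values),
                         specimens = colnames(values)) {
  m <- as.matrix(values)
  if (!is.numeric(m)) stop("values must be numeric")
  if (any(m < 0)) stop("negative entries are not allowed")
  if (is.null(regions)) regions <- paste0("region_", seq_len(nrow(m)))
  if (is.null(specimens)) specimens <- paste0("specimen_", seq_len(ncol(m)))
  dimnames(m) <- list(regions, specimens)
  structure(list(values = m), class = "region_table")
}

#' @export
print.region_table <- function(x, ...) {
  cat(sprintf("<region_table> %d regions x %d specimens\n",
              nrow(x$values), ncol(x$values)))
  print(x$values)
  invisible(x)
}

#' Read / write a region table as CSV
#'
#' First column `region`, one further column per specimen. A trailing
#' `Total` row, if present on read, is validated against the column sums
#' and dropped.
#'
#' @param file CSV path.
#' @param t a [region_table()].
#' @param total append a `Total` row on write.
#' @export
read_region_table <- function(file) {
  d <- read.csv(file, check.names = FALSE)
  regions <- d[[1]]
  m <- as.matrix(d[-1])
  if (tolower(regions[length(regions)]) == "total") {
    body <- m[-nrow(m), , drop = FALSE]
    if (!isTRUE(all.equal(unname(colSums(body)), unname(m[nrow(m), ]))))
      stop("Total row does not equal the column sums of the region rows")
    m <- body; regions <- regions[-length(regions)]
  }
  region_table(m, regions = regions)
}

#' @rdname read_region_table
#' @export
write_region_table <- function(t, file, total = FALSE) {
  stopifnot(inherits(t, "region_table"))
  m <- t$values
  if (total) m <- rbind(m, Total = colSums(m))
  d <- data.frame(region = rownames(m), m, check.names = FALSE)
  write.csv(d, file, row.names = FALSE)
  invisible(file)
}

#' Bundled five-specimen brain tables
#'
#' The package's reference cross-specimen dataset: per-region cell-nucleus
#' counts (`zf_table2()`) and per-region brain volumes in um^3
#' (`zf_table3()`) for five 5-dpf larval zebrafish, nine brain divisions
#' each.
#'
#' @return a [region_table()].
#' @export
zf_table2 <- function() {
  read_region_table(system.file("extdata", "table2_counts.csv",
                                package = "histotomo", mustWork = TRUE))
}

#' @rdname zf_table2
#' @export
zf_table3 <- function() {
  read_region_table(system.file("extdata", "table3_volumes_um3.csv",
                                package = "histotomo", mustWork = TRUE))
}

#' Per-specimen totals of a region table
#'
#' @param t a [region_table()].
#' @return named numeric vector, one total per specimen.
#' @export
specimen_totals <- function(t) {
  stopifnot(inherits(t, "region_table"))
  if (nrow(t$values) == 0 || ncol(t$values) == 0) stop("empty region table")
  colSums(t$values)
}

#' Cross-specimen summary statistics
#'
#' Mean, sample SD (n-1 denominator) and relative SD (100 * SD / mean) per
#' region and for the per-specimen totals. Values are kept at full
#' precision; report-time rounding (mean to integer, RSD to one decimal
#' with round-half-even) is applied only by [format()]/export helpers.
#'
#' @param t a [region_table()] with at least 2 specimens.
#' @return object of class `cohort_summary`: list with `per_region`
#'   (data.frame: region, mean, sd, rsd_pct) and `total` (list: mean, sd,
#'   rsd_pct, n).
#' @export
cohort_summary <- function(t) {
  stopifnot(inherits(t, "region_table"))
  n <- ncol(t$values)
  if (n < 2) stop("cohort summary requires at least 2 specimens")
  per <- data.frame(region = rownames(t$values),
                    mean = rowMeans(t$values),
                    sd = apply(t$values, 1, sd))
  per$rsd_pct <- 100 * per$sd / per$mean
  rownames(per) <- NULL
  tot <- specimen_totals(t)
  structure(list(per_region = per,
                 total = list(mean = mean(tot), sd = sd(tot),
                              rsd_pct = 100 * sd(tot) / mean(tot), n = n)),
            class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf("<cohort_summary> n = %d specimens\n", x$total$n))
  cat(sprintf("  total: mean %s, SD %s, RSD %.1f%%\n",
              format(round(x$total$mean), big.mark = ","),
              format(round(x$total$sd), big.mark = ","), x$total$rsd_pct))
  invisible(x)
}

#' Region proportions, rank orders and cross-specimen concordance
#'
#' Converts each specimen's counts to proportions of its total, ranks the
#' regions within each specimen (rank 1 = largest share; ties broken by
#' region index), and reports pairwise concordance between specimens as
#' Spearman rank correlation and top-k agreement.
#'
#' @param t a [region_table()]; every specimen total must be positive.
#' @param top_k size of the head compared for top-k agreement.
#' @return list with `proportions` (regions x specimens, columns sum to 1),
#'   `ranks` (regions x specimens, dense), `spearman` and `top_k_agreement`
#'   (specimen x specimen matrices), and `fully_tied` (logical: all
#'   proportions equal within a specimen).
#' @export
proportion_ranks <- function(t, top_k = 2L) {
  stopifnot(inherits(t, "region_table"))
  tot <- specimen_totals(t)
  if (any(tot <= 0)) stop("every specimen total must be positive")
  prop <- sweep(t$values, 2, tot, "/")
  ranks <- apply(prop, 2, function(p)
    rank(-p, ties.method = "first"))
  dimnames(ranks) <- dimnames(prop)
  ns <- ncol(prop)
  rho <- matrix(1, ns, ns, dimnames = list(colnames(prop), colnames(prop)))
  agree <- matrix(1, ns, ns, dimnames = dimnames(rho))
  for (i in seq_len(ns)) for (j in seq_len(ns)) {
    rho[i, j] <- suppressWarnings(cor(prop[, i], prop[, j], method = "spearman"))
    ti <- rownames(prop)[order(ranks[, i])][seq_len(top_k)]
    tj <- rownames(prop)[order(ranks[, j])][seq_len(top_k)]
    agree[i, j] <- length(intersect(ti, tj)) / top_k
  }
  fully_tied <- apply(prop, 2, function(p) diff(range(p)) < 1e-12)
  list(proportions = prop, ranks = ranks, spearman = rho,
       top_k_agreement = agree, fully_tied = fully_tied)
}

#' Export an analysis bundle as CSV tables and a JSON summary
#'
#' Deterministic file outputs: the region table as CSV, the cohort summary
#' and run parameters as versioned JSON. The JSON totals always equal the
#' CSV column sums.
#'
#' @param table a [region_table()].
#' @param dir output directory (created if missing).
#' @param params optional named list of run parameters/seeds to log.
#' @param prefix file-name prefix.
#' @return named character vector of the files written.
#' @export
export_report <- function(table, dir, params = list(), prefix = "report") {
  stopifnot(inherits(table, "region_table"))
  if (!dir.exists(dir) &&
      !dir.create(dir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory ", dir)
  csv <- file.path(dir, paste0(prefix, "_regions.csv"))
  write_region_table(table, csv, total = TRUE)
  smry <- cohort_summary(table)
  js <- file.path(dir, paste0(prefix, "_summary.json"))
  jsonlite::write_json(list(
    schema = "histotomo/report@1",
    params = params,
    totals = as.list(specimen_totals(table)),
    total_mean = round(smry$total$mean),
    total_sd = round(smry$total$sd),
    total_rsd_pct = round(smry$total$rsd_pct, 1),
    per_region = smry$per_region
  ), js, auto_unbox = TRUE, digits = NA)
  c(csv = csv, json = js)
}
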