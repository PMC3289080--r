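# File I/O: mzXML MS1 scans, TSV peptide lists, TSV result tables, and the
# preprocessing cache.

#' Read MS1 scans from an mzXML file
#'
#' Decoding (base64, 32/64-bit network byte order, optional zlib) is done by
#' the proteowizard backend of \pkg{mzR}; only msLevel-1 scans are retained,
#' retention times are in seconds, and scans are ordered by retention time.
#' A pre-pass through \pkg{xml2} turns malformed XML into a parse error that
#' names the offending position.
#'
#' @param path Path to an mzXML file.
#' @return An object of class `scan_collection`: list with `times` (seconds,
#'   increasing), `mz` and `intensity` (lists of per-scan numeric vectors,
#'   m/z ascending within each scan).
#' @export
read_mzxml <- function(path) {
  if (!file.exists(path)) stop(sprintf("mzXML file not found: %s", path))
  tryCatch(invisible(xml2::read_xml(path)), error = function(e) {
    stop(sprintf("malformed mzXML in %s: %s", path, conditionMessage(e)))
  })
  h <- NULL
  ms <- mzR::openMSfile(path)
  on.exit(mzR::close(ms))
  h <- mzR::header(ms)
  ms1 <- which(h$msLevel == 1L)
  if (length(ms1) == 0L) stop(sprintf("no MS1 scans in %s", path))
  pk <- mzR::peaks(ms, ms1)
  if (is.matrix(pk)) pk <- list(pk)
  rt <- h$retentionTime[ms1]
  o <- order(rt)
  scan_collection(rt[o], lapply(pk[o], function(m) m[, 1]),
                  lapply(pk[o], function(m) m[, 2]))
}

#' Construct a scan collection
#'
#' @param times Retention times in seconds (one per MS1 scan).
#' @param mz List of per-scan m/z vectors, each sorted ascending.
#' @param intensity List of per-scan intensity vectors (non-negative), same
#'   lengths as `mz`.
#' @return An object of class `scan_collection`.
#' @export
scan_collection <- function(times, mz, intensity) {
  times <- as.numeric(times)
  stopifnot(length(times) == length(mz), length(mz) == length(intensity))
  if (length(times) > 1L && any(diff(times) <= 0)) {
    stop("retention times must be strictly increasing")
  }
  for (i in seq_along(mz)) {
    mz[[i]] <- as.numeric(mz[[i]]); intensity[[i]] <- as.numeric(intensity[[i]])
    if (length(mz[[i]]) != length(intensity[[i]])) {
      stop(sprintf("scan %d: m/z and intensity lengths differ", i))
    }
    if (any(intensity[[i]] < 0)) stop(sprintf("scan %d: negative intensity", i))
    if (is.unsorted(mz[[i]])) {
      o <- order(mz[[i]])
      mz[[i]] <- mz[[i]][o]; intensity[[i]] <- intensity[[i]][o]
    }
  }
  structure(list(times = times, mz = mz, intensity = intensity),
            class = "scan_collection")
}

#' @export
print.scan_collection <- function(x, ...) {
  cat(sprintf("<scan_collection> %d MS1 scans, rt %.1f-%.1f s\n",
              length(x$times), min(x$times), max(x$times)))
  invisible(x)
}

.PEPTIDE_COLS <- c("sequence", "charge", "elution_time", "probability")

#' Read an identified-peptide list (TSV)
#'
#' Expects header columns `sequence`, `charge`, `elution_time`,
#' `probability` (a PeptideProphet-style posterior); extra columns are
#' ignored. Any row violating the record invariants aborts the read with a
#' message naming the row.
#'
#' @param path Path to a TSV file.
#' @return Data frame of validated peptide records, in file order.
#' @export
read_peptide_list <- function(path) {
  if (!file.exists(path)) stop(sprintf("peptide list not found: %s", path))
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                          colClasses = "character", check.names = FALSE)
  missing <- setdiff(.PEPTIDE_COLS, names(df))
  if (length(missing)) {
    stop(sprintf("peptide list %s lacks column(s): %s", path,
                 paste(missing, collapse = ", ")))
  }
  df <- df[, .PEPTIDE_COLS]
  n <- nrow(df)
  num <- function(col) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v))
    if (length(bad)) {
      stop(sprintf("row %d: unparsable %s value '%s'", bad[1], col,
                   df[[col]][bad[1]]))
    }
    v
  }
  charge <- num("charge")
  elution_time <- num("elution_time")
  probability <- num("probability")
  alphabet <- rownames(.residue_comp)
  for (i in seq_len(n)) {
    s <- df$sequence[i]
    if (is.na(s) || nchar(s) == 0L) stop(sprintf("row %d: empty sequence", i))
    bad <- setdiff(strsplit(s, "")[[1]], alphabet)
    if (length(bad)) {
      stop(sprintf("row %d: non-residue character '%s' in sequence '%s'",
                   i, bad[1], s))
    }
    if (charge[i] < 1 || charge[i] != round(charge[i])) {
      stop(sprintf("row %d: charge must be a positive integer, got '%s'",
                   i, df$charge[i]))
    }
    if (probability[i] < 0 || probability[i] > 1) {
      stop(sprintf("row %d: probability %.4g outside [0, 1]", i,
                   probability[i]))
    }
  }
  data.frame(sequence = df$sequence, charge = as.integer(charge),
             elution_time = elution_time, probability = probability,
             stringsAsFactors = FALSE)
}

.RESULT_COLS <- c("sequence", "abundance_before", "correctable",
                  "abundance_after", "fold_change", "p_value")

#' Write a per-peptide fold-change result table (TSV)
#'
#' Six columns: `sequence`; `abundance_before` and `abundance_after` hold
#' both datasets' integrated abundances as a comma-joined pair
#' (`"a1,a2"`); `correctable`; `fold_change` (dataset 2 / dataset 1);
#' `p_value`. Floating values are written at 6 significant digits. For
#' peptides that are not correctable the after-correction abundances equal
#' the before-correction abundances.
#'
#' @param results Data frame as produced by [assign_significance()], with
#'   columns `sequence`, `abundance_before_1`, `abundance_before_2`,
#'   `correctable`, `abundance_after_1`, `abundance_after_2`, `fold_change`,
#'   `p_value`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_results <- function(results, path) {
  if (is.null(results) || nrow(results) == 0L) {
    stop("results must be non-empty")
  }
  fmt <- function(x) sprintf("%.6g", x)
  pair <- function(a, b) paste(fmt(a), fmt(b), sep = ",")
  out <- data.frame(
    sequence = results$sequence,
    abundance_before = pair(results$abundance_before_1,
                            results$abundance_before_2),
    correctable = results$correctable,
    abundance_after = pair(results$abundance_after_1,
                           results$abundance_after_2),
    fold_change = fmt(results$fold_change),
    p_value = fmt(results$p_value),
    stringsAsFactors = FALSE)
  tryCatch(
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE),
    error = function(e) stop(sprintf("cannot write results to %s: %s", path,
                                     conditionMessage(e))))
  invisible(path)
}

#' Read back a fold-change result table
#'
#' Inverse of [write_results()] (to the 6 significant digits written).
#'
#' @param path TSV path written by [write_results()].
#' @return Data frame with the unpacked per-dataset abundance columns.
#' @export
read_results <- function(path) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  missing <- setdiff(.RESULT_COLS, names(df))
  if (length(missing)) {
    stop(sprintf("result file lacks column(s): %s",
                 paste(missing, collapse = ", ")))
  }
  split2 <- function(col) {
    m <- do.call(rbind, strsplit(as.character(col), ",", fixed = TRUE))
    cbind(as.numeric(m[, 1]), as.numeric(m[, 2]))
  }
  ab <- split2(df$abundance_before)
  aa <- split2(df$abundance_after)
  data.frame(sequence = df$sequence,
             abundance_before_1 = ab[, 1], abundance_before_2 = ab[, 2],
             correctable = as.logical(df$correctable),
             abundance_after_1 = aa[, 1], abundance_after_2 = aa[, 2],
             fold_change = as.numeric(df$fold_change),
             p_value = as.numeric(df$p_value),
             stringsAsFactors = FALSE)
}

#' Write a preprocessing cache
#'
#' Stores per-peptide XIC pairs, peak intervals and isotope ratios keyed by
#' the MD5 checksums of the source mzXML and peptide-list files, so repeated
#' analyses skip the (slow) scan decode. One self-describing RDS file per
#' dataset.
#'
#' @param entries List of per-peptide entries (see [cmd_preprocess()]).
#' @param mzxml_path,peptide_list_path Source files, checksummed into the
#'   cache key.
#' @param path Output cache path.
#' @return `path`, invisibly.
#' @export
write_cache <- function(entries, mzxml_path, peptide_list_path, path) {
  key <- c(mzxml = unname(tools::md5sum(mzxml_path)),
           peptides = unname(tools::md5sum(peptide_list_path)))
  obj <- list(format = "supcorr-cache", version = 1L, key = key,
              entries = entries)
  saveRDS(obj, path, version = 2, compress = "gzip")
  invisible(path)
}

#' Load a preprocessing cache
#'
#' @param path Cache path written by [write_cache()].
#' @return The cache object (fields `key` and `entries`).
#' @export
read_cache <- function(path) {
  if (!file.exists(path)) stop(sprintf("cache not found: %s", path))
  obj <- readRDS(path)
  if (!identical(obj$format, "supcorr-cache")) {
    stop(sprintf("%s is not a supcorr preprocessing cache", path))
  }
  obj
}
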