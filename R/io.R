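#' Read and write force-curve files
#'
#' The on-disk dialect is one file per curve: header lines beginning `#`
#' holding `key=value` pairs (`curve_id`, `sample_id`, `probe`, `substrate`,
#' `spring_constant_N_per_m`, `bead_radius_um`), followed by a TSV body with
#' columns `segment`, `piezo_height_nm`, `force_pN`. Reader and writer
#' round-trip losslessly (forces and heights serialised at full double
#' precision).
#'
#' @param path file path.
#' @return `readForceCurve` returns a [ForceCurve]; `writeForceCurve`
#'   returns `path` invisibly.
#' @export
readForceCurve <- function(path) {
  if (!file.exists(path)) stop(sprintf("force-curve file not found: %s", path))
  lines <- readLines(path)
  isHead <- startsWith(lines, "#")
  nHead <- if (any(!isHead)) which(!isHead)[1] - 1L else length(lines)
  head <- sub("^#\\s*", "", lines[seq_len(nHead)])
  kv <- strsplit(head, "=", fixed = TRUE)
  bad <- which(lengths(kv) != 2L)
  if (length(bad))
    stop(sprintf("malformed header line %d in %s: '%s'", bad[1], path, head[bad[1]]))
  keys <- vapply(kv, `[`, character(1), 1L)
  vals <- vapply(kv, `[`, character(1), 2L)
  meta <- stats::setNames(trimws(vals), trimws(keys))
  need <- c("curve_id", "sample_id", "probe", "substrate", "spring_constant_N_per_m")
  miss <- setdiff(need, names(meta))
  if (length(miss))
    stop(sprintf("missing header key(s) in %s: %s", path, paste(miss, collapse = ", ")))
  body <- utils::read.table(text = lines[!isHead], header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
  segs <- lapply(split(body, factor(body$segment, levels = unique(body$segment))),
                 function(d) FDSegment(d$segment[1], d$piezo_height_nm, d$force_pN))
  ForceCurve(curveId = meta[["curve_id"]], sampleId = meta[["sample_id"]],
             probe = meta[["probe"]], substrate = meta[["substrate"]],
             springConstant = as.numeric(meta[["spring_constant_N_per_m"]]),
             beadRadius = if ("bead_radius_um" %in% names(meta))
               as.numeric(meta[["bead_radius_um"]]) else NA_real_,
             segments = unname(segs))
}

#' @rdname readForceCurve
#' @param curve a [ForceCurve].
#' @export
writeForceCurve <- function(curve, path) {
  stopifnot(is(curve, "ForceCurve"))
  head <- c(
    sprintf("# curve_id=%s", curve@curveId),
    sprintf("# sample_id=%s", curve@sampleId),
    sprintf("# probe=%s", curve@probe),
    sprintf("# substrate=%s", curve@substrate),
    sprintf("# spring_constant_N_per_m=%s", format(curve@springConstant, digits = 17)),
    sprintf("# bead_radius_um=%s",
            if (is.na(curve@beadRadius)) "NA" else format(curve@beadRadius, digits = 17)))
  rows <- unlist(lapply(curve@segments, function(s)
    sprintf("%s\t%s\t%s", s@label,
            format(s@piezoHeight, digits = 17, trim = TRUE, scientific = FALSE),
            format(s@force, digits = 17, trim = TRUE, scientific = FALSE))))
  writeLines(c(head, "segment\tpiezo_height_nm\tforce_pN", rows), path)
  invisible(path)
}

#' Write a data.frame as TSV with a provenance header
#'
#' All pipeline outputs are TSV files whose leading `#` lines record the
#' run parameters (including the seed), so that a result can always be
#' traced to its configuration. No timestamps are written: identical runs
#' produce byte-identical files.
#'
#' @param df data.frame.
#' @param path output path.
#' @param provenance named list of parameters recorded as `# key=value`.
#' @return `path`, invisibly.
#' @export
writeProvenanceTSV <- function(df, path, provenance = list()) {
  head <- vapply(names(provenance), function(k)
    sprintf("# %s=%s", k, paste(format(provenance[[k]], digits = 15), collapse = ",")),
    character(1))
  con <- file(path, "w")
  on.exit(close(con))
  if (length(head)) writeLines(unname(head), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeProvenanceTSV
#' @export
readProvenanceTSV <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                    stringsAsFactors = FALSE)
}

#' Read and write rupture-event tables
#'
#' Event tables are TSV with columns `curve_id`, `rupture_force_pN`,
#' `rupture_length_nm` plus `sample_id`, `probe`, `substrate`,
#' `stiffness_class` and `n_curves_total` recorded in the provenance header.
#'
#' @param eventSet an [EventSet].
#' @param path file path.
#' @return `readEventTable` returns an [EventSet].
#' @export
writeEventTable <- function(eventSet, path) {
  stopifnot(is(eventSet, "EventSet"))
  ev <- eventSet@events
  df <- data.frame(curve_id = ev$curveId,
                   rupture_force_pN = ev$ruptureForce,
                   rupture_length_nm = ev$ruptureLength)
  if ("specific" %in% names(ev)) df$specific <- ev$specific
  writeProvenanceTSV(df, path, provenance = list(
    sample_id = eventSet@sampleId, probe = eventSet@probe,
    substrate = eventSet@substrate, stiffness_class = eventSet@stiffnessClass,
    n_curves_total = eventSet@nCurvesTotal))
  invisible(path)
}

#' @rdname writeEventTable
#' @export
readEventTable <- function(path) {
  if (!file.exists(path)) stop(sprintf("event table not found: %s", path))
  lines <- readLines(path)
  head <- sub("^#\\s*", "", lines[startsWith(lines, "#")])
  kv <- strsplit(head, "=", fixed = TRUE)
  meta <- stats::setNames(vapply(kv, `[`, character(1), 2L),
                          vapply(kv, `[`, character(1), 1L))
  df <- readProvenanceTSV(path)
  ev <- data.frame(curveId = as.character(df$curve_id),
                   ruptureForce = df$rupture_force_pN,
                   ruptureLength = df$rupture_length_nm)
  if ("specific" %in% names(df)) ev$specific <- df$specific
  EventSet(ev, sampleId = meta[["sample_id"]], probe = meta[["probe"]],
           substrate = meta[["substrate"]],
           stiffnessClass = meta[["stiffness_class"]],
           nCurvesTotal = as.integer(meta[["n_curves_total"]]))
}
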