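#' Normalise marker names
#'
#' Maps common spelling variants (e.g. `PD-1`, `HLA-DR`, `CTLA-4`,
#' `4-1BB`, `Fas`, `Galectin-9`) onto the canonical names used
#' throughout the package. Unrecognised names are returned unchanged.
#' Matching ignores case, hyphens, underscores and spaces.
#'
#' @param x Character vector of marker names.
#' @return Character vector of the same length.
#' @examples
#' normalizeMarkerNames(c("PD-1", "HLA-DR", "4-1BBL", "FasL", "CD3"))
#' @export
normalizeMarkerNames <- function(x) {
  key <- toupper(gsub("[-_ ‐‑‒–]", "", x))
  map <- c(PD1 = "PD1", PDL1 = "PDL1", PDL2 = "PDL2", HLADR = "HLADR",
           CTLA4 = "CTLA4", TIM3 = "TIM3", LAG3 = "LAG3", OX40 = "OX40",
           OX40L = "OX40L", "41BB" = "CD137", "41BBL" = "CD137L",
           CD137 = "CD137", CD137L = "CD137L", FAS = "CD95",
           FASL = "CD95L", CD95 = "CD95", CD95L = "CD95L",
           GALECTIN9 = "GAL9", GAL9 = "GAL9", ICOSL = "ICOSL",
           ICOS = "ICOS", CXCR5 = "CXCR5", TIGIT = "TIGIT", PVR = "PVR",
           BTLA = "BTLA", HVEM = "HVEM", CD40L = "CD40L", CD40 = "CD40")
  hit <- key %in% names(map)
  x[hit] <- unname(map[key[hit]])
  x
}

.FCS_HEADER_LEN <- 58L

#' Write event data
#'
#' Writes a [CytoFrame-class] either as an FCS 3.0 file (list mode,
#' 32-bit floats, little-endian, linear `$PnE`) or as a plain CSV
#' (UTF-8, comma separator, header row of channel names, `.` decimal
#' mark). FCS keywords record the marker name in `$PnS`, the software
#' version and, when given, the simulation seed, so files carry their
#' provenance.
#'
#' @param frame A [CytoFrame-class].
#' @param path Output file path.
#' @param dialect `"fcs3"` or `"csv"`.
#' @param seed Optional integer recorded in the FCS `FLOWSDC_SEED`
#'   keyword.
#' @return `path`, invisibly.
#' @export
writeEvents <- function(frame, path, dialect = c("fcs3", "csv"),
                        seed = NULL) {
  stopifnot(is(frame, "CytoFrame"))
  dialect <- match.arg(dialect)
  e <- exprs(frame)
  if (dialect == "csv") {
    utils::write.csv(as.data.frame(e), path, row.names = FALSE,
                     fileEncoding = "UTF-8")
    return(invisible(path))
  }
  if (any(grepl("/", colnames(e), fixed = TRUE)))
    stop("channel names must not contain the FCS delimiter '/'")
  n <- nrow(e); p <- ncol(e)
  kw <- c("$BEGINANALYSIS" = "0", "$ENDANALYSIS" = "0",
          "$BEGINSTEXT" = "0", "$ENDSTEXT" = "0",
          "$BEGINDATA" = "@BD@", "$ENDDATA" = "@ED@",
          "$BYTEORD" = "1,2,3,4", "$DATATYPE" = "F", "$MODE" = "L",
          "$NEXTDATA" = "0", "$PAR" = as.character(p),
          "$TOT" = as.character(n),
          "$FIL" = basename(path), "SOFTWARE" = .softwareTag())
  if (!is.null(seed)) kw <- c(kw, FLOWSDC_SEED = as.character(seed))
  rng <- if (n) apply(e, 2, max) else rep(1, p)
  for (j in seq_len(p)) {
    nm <- colnames(e)[j]
    kw <- c(kw,
      stats::setNames(c(nm, nm, "32", "0,0",
                        as.character(ceiling(max(rng[j], 1)))),
        sprintf(c("$P%dN", "$P%dS", "$P%dB", "$P%dE", "$P%dR"), j)))
  }
  text <- paste0("/", paste0(names(kw), "/", kw, "/", collapse = ""))
  textStart <- .FCS_HEADER_LEN
  # $BEGINDATA/$ENDDATA use fixed 10-digit placeholders so the TEXT
  # length does not depend on the values substituted in
  textLen <- nchar(text, type = "bytes") + 2L * (10L - 4L)
  dataStart <- textStart + textLen
  dataEnd <- dataStart + 4L * n * p - 1L
  if (n == 0L) dataEnd <- 0L
  text <- sub("@BD@", sprintf("%010d", dataStart), text, fixed = TRUE)
  text <- sub("@ED@", sprintf("%010d", dataEnd), text, fixed = TRUE)
  if (dataEnd > 99999999)
    stop("data segment too large for this FCS 3.0 writer")
  header <- sprintf("FCS3.0    %8d%8d%8d%8d%8d%8d",
                    textStart, textStart + textLen - 1L,
                    dataStart, dataEnd, 0L, 0L)
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(header, con, eos = NULL)
  writeChar(text, con, eos = NULL)
  if (n) writeBin(as.vector(t(e)), con, size = 4L, endian = "little")
  invisible(path)
}

.softwareTag <- function() {
  ver <- tryCatch(as.character(utils::packageVersion("flowSDC")),
                  error = function(e) "dev")
  paste0("flowSDC ", ver)
}

#' Read event data
#'
#' Reads an FCS 3.0 file or a CSV event table into a
#' [CytoFrame-class]. For FCS, channel names are taken from `$PnS` when
#' present, falling back to `$PnN`; marker-name spelling variants are
#' normalised via [normalizeMarkerNames()]. Values are returned exactly
#' as stored - no transformation is applied. A channel named `Time` (any
#' case) is designated the acquisition-time channel.
#'
#' @param path File to read.
#' @param dialect `"auto"` (by file extension), `"fcs3"` or `"csv"`.
#' @return A [CytoFrame-class].
#' @export
readEvents <- function(path, dialect = c("auto", "fcs3", "csv")) {
  dialect <- match.arg(dialect)
  if (dialect == "auto")
    dialect <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "fcs3"
  if (dialect == "csv") {
    d <- utils::read.csv(path, check.names = FALSE, fileEncoding = "UTF-8")
    e <- as.matrix(d)
    if (!is.numeric(e)) stop("CSV event table must be numeric")
    colnames(e) <- normalizeMarkerNames(colnames(e))
  } else {
    e <- .readFCS(path)
  }
  if (any(is.na(e))) stop("event data contain missing values after load")
  tc <- colnames(e)[tolower(colnames(e)) == "time"][1]
  CytoFrame(e, sampleId = sub("\\.(fcs|csv)$", "", basename(path),
                              ignore.case = TRUE),
            timeChannel = if (is.na(tc)) NA_character_ else tc)
}

.readFCS <- function(path) {
  sz <- file.info(path)$size
  if (is.na(sz) || sz < .FCS_HEADER_LEN) stop("truncated FCS file")
  con <- file(path, "rb")
  on.exit(close(con))
  header <- readChar(con, .FCS_HEADER_LEN, useBytes = TRUE)
  if (substr(header, 1, 6) != "FCS3.0")
    stop("not an FCS 3.0 file")
  off <- suppressWarnings(as.integer(substring(
    header, 10 + 8 * (0:3) + 1, 10 + 8 * (1:4))))
  if (any(is.na(off[1:2]))) stop("unparsable FCS header offsets")
  seek(con, off[1])
  text <- readChar(con, off[2] - off[1] + 1L, useBytes = TRUE)
  delim <- substr(text, 1, 1)
  parts <- strsplit(substring(text, 2), delim, fixed = TRUE)[[1]]
  if (length(parts) %% 2L == 1L) parts <- parts[-length(parts)]
  kw <- stats::setNames(parts[seq(2, length(parts), 2)],
                        toupper(parts[seq(1, length(parts), 2)]))
  need <- c("$PAR", "$TOT", "$DATATYPE", "$BYTEORD")
  if (!all(need %in% names(kw)))
    stop("missing required FCS keywords: ",
         paste(setdiff(need, names(kw)), collapse = ", "))
  if (toupper(kw[["$DATATYPE"]]) != "F")
    stop("only $DATATYPE F (float) is supported")
  endian <- switch(kw[["$BYTEORD"]],
                   "1,2,3,4" = "little", "4,3,2,1" = "big",
                   stop("unsupported $BYTEORD"))
  kwGet <- function(name) if (name %in% names(kw)) kw[[name]] else NULL
  p <- as.integer(kw[["$PAR"]]); n <- as.integer(kw[["$TOT"]])
  dataStart <- as.integer(kwGet("$BEGINDATA") %||% off[3])
  dataEnd <- as.integer(kwGet("$ENDDATA") %||% off[4])
  if (dataStart == 0L) { dataStart <- off[3]; dataEnd <- off[4] }
  nbytes <- if (n == 0L) 0L else dataEnd - dataStart + 1L
  if (nbytes != 4L * n * p)
    stop("channel count mismatch between header and data segment")
  if (n > 0 && sz < dataStart + nbytes) stop("truncated FCS file")
  nm <- vapply(seq_len(p), function(j) {
    s <- kwGet(sprintf("$P%dS", j))
    if (!is.null(s) && nzchar(s)) s
    else kwGet(sprintf("$P%dN", j)) %||% sprintf("P%d", j)
  }, character(1))
  vals <- if (n == 0L) numeric(0) else {
    seek(con, dataStart)
    readBin(con, "numeric", n = n * p, size = 4L, endian = endian)
  }
  matrix(vals, nrow = n, ncol = p, byrow = TRUE,
         dimnames = list(NULL, normalizeMarkerNames(nm)))
}

#' Read a sample sheet
#'
#' CSV with required columns `sample_id` and `group` (optionally `file`,
#' `panel` and any user columns, which are preserved). Errors on missing
#' required columns or duplicate sample ids; optionally checks group
#' labels against a declared set.
#'
#' @param path CSV file.
#' @param groups Optional character vector of allowed group labels.
#' @return A data.frame.
#' @export
readSampleSheet <- function(path, groups = NULL) {
  d <- utils::read.csv(path, check.names = FALSE, fileEncoding = "UTF-8",
                       stringsAsFactors = FALSE)
  miss <- setdiff(c("sample_id", "group"), names(d))
  if (length(miss))
    stop("sample sheet missing required column(s): ",
         paste(miss, collapse = ", "))
  if (anyDuplicated(d$sample_id))
    stop("duplicate sample_id in sample sheet")
  if (!is.null(groups) && !all(d$group %in% groups))
    stop("sample sheet contains undeclared group labels: ",
         paste(setdiff(d$group, groups), collapse = ", "))
  d
}

#' Read a ligand-receptor catalogue
#'
#' CSV with required columns `ligand` and `receptor` (optionally
#' `direction`); marker spellings are normalised and duplicate ordered
#' pairs rejected.
#'
#' @param path CSV file.
#' @return A data.frame of unique ordered ligand-receptor pairs.
#' @export
readLRCatalogue <- function(path) {
  d <- utils::read.csv(path, check.names = FALSE, fileEncoding = "UTF-8",
                       stringsAsFactors = FALSE)
  miss <- setdiff(c("ligand", "receptor"), names(d))
  if (length(miss))
    stop("LR catalogue missing required column(s): ",
         paste(miss, collapse = ", "))
  d$ligand <- normalizeMarkerNames(d$ligand)
  d$receptor <- normalizeMarkerNames(d$receptor)
  if (anyDuplicated(d[, c("ligand", "receptor")]))
    stop("duplicate ligand-receptor pairs in catalogue")
  d
}

#' The default ligand-receptor catalogue
#'
#' Immune co-stimulatory / co-inhibitory axes resolvable on typical
#' T-cell and tumor-microenvironment spectral panels (ICOS-ICOSL,
#' CTLA4-CD80/CD86, PD1-PDL1/PDL2, OX40-OX40L, CD137-CD137L, TIGIT-PVR,
#' CD95-CD95L, BTLA-HVEM, TIM3-GAL9, CD40L-CD40, CD28-CD80/CD86).
#' Shipped as a plain CSV; user catalogues can be loaded with
#' [readLRCatalogue()] instead.
#'
#' @return A data.frame with columns `ligand`, `receptor`, `direction`.
#' @export
defaultLRCatalogue <- function() {
  readLRCatalogue(system.file("extdata", "lr_catalogue.csv",
                              package = "flowSDC", mustWork = TRUE))
}
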