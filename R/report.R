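#' Assemble a report bundle
#'
#' Writes each table of a (possibly partial) analysis to CSV in
#' `outdir`, together with a `manifest.json` listing every expected
#' stage and whether it is present, and a `run.log` recording seeds and
#' parameters. Reruns with identical inputs produce byte-identical
#' files (no timestamps are written).
#'
#' @param tables Named list of data.frames (entries may be `NULL` for
#'   stages that were not run; they are marked absent in the manifest
#'   rather than failing).
#' @param outdir Output directory (created if needed).
#' @param runInfo Named list of seeds/parameters recorded in the
#'   manifest and log.
#' @return Invisibly, the manifest as a list.
#' @export
buildReport <- function(tables, outdir, runInfo = list()) {
  if (!dir.exists(outdir) &&
      !dir.create(outdir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory: ", outdir)
  entries <- lapply(names(tables), function(nm) {
    tb <- tables[[nm]]
    if (is.null(tb)) return(list(table = nm, present = FALSE))
    fn <- paste0(nm, ".csv")
    utils::write.csv(tb, file.path(outdir, fn), row.names = FALSE)
    list(table = nm, present = TRUE, file = fn,
         rows = nrow(tb), cols = ncol(tb))
  })
  manifest <- list(package = .softwareTag(), run = runInfo,
                   tables = entries)
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  log <- c(paste0("package: ", .softwareTag()),
           vapply(names(runInfo), function(k)
             paste0(k, ": ", paste(format(runInfo[[k]]), collapse = " ")),
             character(1)),
           paste0("tables: ", paste(vapply(entries, function(e)
             sprintf("%s[%s]", e$table,
                     if (isTRUE(e$present)) "present" else "absent"),
             character(1)), collapse = ", ")))
  writeLines(log, file.path(outdir, "run.log"))
  invisible(manifest)
}
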