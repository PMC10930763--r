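#' Read and write cohort tables
#'
#' Expression is written genes-as-rows with sample ids as columns (the GDC
#' matrix convention, first column `gene`); clinical tables carry the columns
#' `sample_id, age, sex, stage, os_months, os_event, site`. Bags are written
#' as one TSV feature matrix per sample plus a JSON manifest mapping sample
#' ids to files and sites.
#'
#' @param expression genes x samples matrix.
#' @param clinical clinical data.frame.
#' @param bags list of [PatchBag-class].
#' @param path,dir file or directory path.
#' @return readers return the parsed object; writers return the path(s)
#'   invisibly.
#' @name cohortIO
NULL

#' @rdname cohortIO
#' @export
writeExpressionTSV <- function(expression, path) {
  df <- data.frame(gene = rownames(expression), expression,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname cohortIO
#' @export
readExpressionTSV <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

#' @rdname cohortIO
#' @export
writeClinicalTSV <- function(clinical, path) {
  utils::write.table(clinical, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname cohortIO
#' @export
readClinicalTSV <- function(path) utils::read.delim(path)

#' @rdname cohortIO
#' @export
writeBags <- function(bags, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  manifest <- lapply(bags, function(b) {
    f <- paste0(b@sampleId, ".tsv")
    utils::write.table(b@features, file.path(dir, f), sep = "\t",
                       quote = FALSE, row.names = FALSE, col.names = FALSE)
    list(sample_id = b@sampleId, file = f, site = b@site,
         n_patches = nrow(b@features))
  })
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE)
  invisible(dir)
}

#' @rdname cohortIO
#' @export
readBags <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = FALSE)
  lapply(manifest, function(m)
    patchBag(m$sample_id,
             as.matrix(utils::read.delim(file.path(dir, m$file),
                                         header = FALSE)),
             site = m$site))
}

#' Serialize a trained AMIL model to text files
#'
#' Writes the parameter matrices as a flat numeric TSV plus a JSON sidecar
#' with shapes, the target scaler, mode and training configuration, and reads
#' them back.
#'
#' @param model an [AmilModel-class].
#' @param path base path (two files are written: `<path>.params.tsv` and
#'   `<path>.json`).
#' @return `writeAmilModel` returns the base path invisibly;
#'   `readAmilModel` the reconstructed [AmilModel-class].
#' @export
writeAmilModel <- function(model, path) {
  shapes <- lapply(model@weights, function(x)
    if (is.matrix(x)) dim(x) else length(x))
  flat <- unlist(model@weights, use.names = FALSE)
  utils::write.table(data.frame(value = flat), paste0(path, ".params.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(shapes = shapes, mode = model@mode,
                            scaler = as.list(model@scaler),
                            config = model@config,
                            history = model@history),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeAmilModel
#' @export
readAmilModel <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  flat <- utils::read.delim(paste0(path, ".params.tsv"))$value
  wts <- list(); off <- 0L
  for (nm in names(meta$shapes)) {
    sh <- meta$shapes[[nm]]
    n <- prod(sh)
    v <- flat[off + seq_len(n)]
    wts[[nm]] <- if (length(sh) == 2) matrix(v, sh[1], sh[2]) else v
    off <- off + n
  }
  new("AmilModel", weights = wts, mode = meta$mode,
      scaler = c(min = as.numeric(meta$scaler$min),
                 max = as.numeric(meta$scaler$max)),
      config = as.list(meta$config), history = as.numeric(meta$history))
}
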