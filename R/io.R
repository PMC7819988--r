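# Dataset interchange.
#
# CSV dialect: one row per peak with columns sample,x,y,mz,intensity (m/z
# and intensity printed with 17 significant digits so doubles round-trip
# exactly), plus a JSON sidecar <stem>.json holding mode, grid size and the
# sample table (id, group, age).
#
# imzML: a minimal imzML 1.1 writer/reader for processed-mode centroided
# spectra (64-bit m/z and intensity arrays in an .ibd file addressed by
# external offsets from the XML). One imzML/ibd pair per sample plus a JSON
# sidecar for the experiment metadata. This is an in-package implementation
# of the interchange format, covering the subset of the standard the
# package emits.

#' Write / read an MSI dataset
#'
#' `write_msi_dataset()` serializes a single-mode `msi_dataset`;
#' `read_msi_dataset()` restores it. The round trip is the identity on
#' coordinates and metadata, exact on intensity, and preserves m/z to
#' better than 1e-9 Da.
#'
#' @param dataset An `msi_dataset`.
#' @param path Output stem: `<path>.csv` + `<path>.json` for CSV, or a
#'   directory for imzML.
#' @param format `"csv"` or `"imzml"`.
#' @return `write_msi_dataset()` the path, invisibly; `read_msi_dataset()`
#'   an `msi_dataset`.
#' @export
write_msi_dataset <- function(dataset, path, format = c("csv", "imzml")) {
  format <- tryCatch(match.arg(format),
                     error = function(e) stop("format error: unknown dataset format '",
                                              format[1], "'", call. = FALSE))
  stopifnot(inherits(dataset, "msi_dataset"))
  meta <- list(format = format, mode = dataset$mode,
               grid_dim = dataset$grid_dim, samples = dataset$samples)
  if (format == "csv") {
    p <- dataset$peaks
    con <- file(paste0(path, ".csv"), "w")
    on.exit(close(con))
    writeLines("sample,x,y,mz,intensity", con)
    writeLines(sprintf("%s,%d,%d,%.17g,%.17g", p$sample_id, p$x, p$y, p$mz,
                       p$intensity), con)
    jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA)
  } else {
    dir.create(path, showWarnings = FALSE, recursive = TRUE)
    for (sid in dataset$samples$sample_id) {
      write_imzml_sample(dataset, sid, file.path(path, sid))
    }
    jsonlite::write_json(meta, file.path(path, "metadata.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' @rdname write_msi_dataset
#' @export
read_msi_dataset <- function(path, format = NULL) {
  if (is.null(format)) {
    format <- if (file.exists(paste0(path, ".csv"))) "csv"
    else if (dir.exists(path) && file.exists(file.path(path, "metadata.json"))) "imzml"
    else stop("format error: cannot identify dataset format at ", path)
  }
  if (format == "csv") {
    meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
    first <- readLines(paste0(path, ".csv"), n = 1L)
    if (!identical(first, "sample,x,y,mz,intensity")) {
      stop("parse error: malformed CSV header in ", paste0(path, ".csv"),
           " (line 1)")
    }
    p <- utils::read.csv(paste0(path, ".csv"), stringsAsFactors = FALSE,
                         colClasses = c("character", "integer", "integer",
                                        "numeric", "numeric"))
    names(p)[1] <- "sample_id"
    new_msi_dataset(p, as.data.frame(meta$samples), meta$mode,
                    unlist(meta$grid_dim))
  } else if (format == "imzml") {
    meta <- jsonlite::read_json(file.path(path, "metadata.json"),
                                simplifyVector = TRUE)
    samples <- as.data.frame(meta$samples)
    parts <- lapply(samples$sample_id, function(sid) {
      sp <- read_imzml_sample(file.path(path, sid))
      sp$sample_id <- sid
      sp[, c("sample_id", "x", "y", "mz", "intensity")]
    })
    p <- do.call(rbind, parts)
    rownames(p) <- NULL
    new_msi_dataset(p, samples, meta$mode, unlist(meta$grid_dim))
  } else {
    stop("format error: unknown dataset format '", format, "'")
  }
}

# ---- minimal imzML 1.1 (processed mode, centroid spectra) ----

imzml_cv <- function(accession, name, value = NULL) {
  v <- if (is.null(value)) "" else sprintf(' value="%s"', value)
  ref <- if (startsWith(accession, "IMS")) "IMS" else "MS"
  sprintf('<cvParam cvRef="%s" accession="%s" name="%s"%s/>', ref, accession,
          name, v)
}

write_imzml_sample <- function(dataset, sample_id, stem) {
  p <- dataset$peaks[dataset$peaks$sample_id == sample_id, , drop = FALSE]
  keys <- unique(p[, c("x", "y")])
  keys <- keys[order(keys$y, keys$x), , drop = FALSE]
  ibd <- file(paste0(stem, ".ibd"), "wb")
  uuid <- as.raw(c(0x6d, 0x73, 0x69, 0x6d, 0x65, 0x74, 0x61, 0x62,
                   seq_len(8)))
  writeBin(uuid, ibd)
  offset <- 16
  specs <- character(nrow(keys))
  pk <- split(seq_len(nrow(p)), paste(p$x, p$y))
  for (i in seq_len(nrow(keys))) {
    idx <- pk[[paste(keys$x[i], keys$y[i])]]
    idx <- idx[order(p$mz[idx])]
    mz <- p$mz[idx]; inten <- p$intensity[idx]
    n <- length(mz)
    writeBin(mz, ibd, size = 8, endian = "little")
    writeBin(inten, ibd, size = 8, endian = "little")
    specs[i] <- paste0(
      sprintf('<spectrum index="%d" id="spectrum=%d" defaultArrayLength="%d">',
              i - 1L, i, n),
      imzml_cv("MS:1000127", "centroid spectrum"),
      '<scanList count="1"><scan>',
      imzml_cv("IMS:1000050", "position x", keys$x[i]),
      imzml_cv("IMS:1000051", "position y", keys$y[i]),
      "</scan></scanList>",
      '<binaryDataArrayList count="2">',
      '<binaryDataArray encodedLength="0">',
      '<referenceableParamGroupRef ref="mzArray"/>',
      imzml_cv("IMS:1000103", "external array length", n),
      imzml_cv("IMS:1000104", "external encoded length", n * 8),
      imzml_cv("IMS:1000102", "external offset", offset),
      "<binary/></binaryDataArray>",
      '<binaryDataArray encodedLength="0">',
      '<referenceableParamGroupRef ref="intensityArray"/>',
      imzml_cv("IMS:1000103", "external array length", n),
      imzml_cv("IMS:1000104", "external encoded length", n * 8),
      imzml_cv("IMS:1000102", "external offset", offset + n * 8),
      "<binary/></binaryDataArray>",
      "</binaryDataArrayList></spectrum>")
    offset <- offset + 16 * n
  }
  close(ibd)
  xml <- paste0(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<mzML xmlns="http://psi.hupo.org/ms/mzml" version="1.1">',
    '<fileDescription><fileContent>',
    imzml_cv("IMS:1000031", "processed"),
    imzml_cv("MS:1000127", "centroid spectrum"),
    "</fileContent></fileDescription>",
    '<referenceableParamGroupList count="2">',
    '<referenceableParamGroup id="mzArray">',
    imzml_cv("MS:1000514", "m/z array"),
    imzml_cv("MS:1000523", "64-bit float"),
    "</referenceableParamGroup>",
    '<referenceableParamGroup id="intensityArray">',
    imzml_cv("MS:1000515", "intensity array"),
    imzml_cv("MS:1000523", "64-bit float"),
    "</referenceableParamGroup>",
    "</referenceableParamGroupList>",
    sprintf('<run id="%s"><spectrumList count="%d">', sample_id, nrow(keys)),
    paste(specs, collapse = ""),
    "</spectrumList></run></mzML>")
  writeLines(xml, paste0(stem, ".imzML"))
  invisible(stem)
}

read_imzml_sample <- function(stem) {
  xml_path <- paste0(stem, ".imzML")
  ibd_path <- paste0(stem, ".ibd")
  if (!file.exists(xml_path) || !file.exists(ibd_path)) {
    stop("parse error: missing imzML/ibd pair at ", stem)
  }
  doc <- tryCatch(xml2::read_xml(xml_path), error = function(e) {
    stop("parse error in ", xml_path, ": ", conditionMessage(e), call. = FALSE)
  })
  xml2::xml_ns_strip(doc)
  specs <- xml2::xml_find_all(doc, ".//spectrum")
  if (!length(specs)) stop("parse error: no spectra in ", xml_path)
  ibd <- file(ibd_path, "rb")
  on.exit(close(ibd))
  out <- vector("list", length(specs))
  for (i in seq_along(specs)) {
    s <- specs[[i]]
    getv <- function(node, acc) {
      v <- xml2::xml_attr(
        xml2::xml_find_first(node, sprintf(".//cvParam[@accession='%s']", acc)),
        "value")
      if (is.na(v)) stop("parse error: missing cvParam ", acc, " in spectrum ",
                         i, " of ", xml_path)
      as.numeric(v)
    }
    x <- getv(s, "IMS:1000050"); y <- getv(s, "IMS:1000051")
    arrays <- xml2::xml_find_all(s, ".//binaryDataArray")
    vals <- list()
    for (a in arrays) {
      ref <- xml2::xml_attr(xml2::xml_find_first(a, "referenceableParamGroupRef"),
                            "ref")
      n <- getv(a, "IMS:1000103"); off <- getv(a, "IMS:1000102")
      seek(ibd, where = off, origin = "start")
      vals[[ref]] <- readBin(ibd, "double", n = n, size = 8,
                             endian = "little")
    }
    if (is.null(vals$mzArray) || is.null(vals$intensityArray)) {
      stop("parse error: spectrum ", i, " lacks m/z or intensity array")
    }
    out[[i]] <- data.frame(x = as.integer(x), y = as.integer(y),
                           mz = vals$mzArray,
                           intensity = vals$intensityArray)
  }
  do.call(rbind, out)
}

#' Write / read a feature matrix
#'
#' CSV of features x samples (mean pixel intensities) with a JSON sidecar
#' holding feature metadata (consensus m/z, mode, annotation) and the
#' sample table.
#'
#' @param fm An `msi_features` object.
#' @param path Output stem (`<path>.csv` + `<path>.json`).
#' @export
write_feature_matrix <- function(fm, path) {
  stopifnot(inherits(fm, "msi_features"))
  m <- as.data.frame(fm$intensity)
  df <- cbind(data.frame(feature_id = rownames(fm$intensity),
                         stringsAsFactors = FALSE), m)
  write.table(df, paste0(path, ".csv"), sep = ",", row.names = FALSE,
              quote = FALSE)
  jsonlite::write_json(list(features = fm$features, samples = fm$samples,
                            logged = isTRUE(fm$logged),
                            imputed_value = fm$imputed_value),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_feature_matrix
#' @export
read_feature_matrix <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  df <- utils::read.csv(paste0(path, ".csv"), stringsAsFactors = FALSE,
                        check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$feature_id
  new_msi_features(m, as.data.frame(meta$features),
                   as.data.frame(meta$samples),
                   logged = isTRUE(meta$logged),
                   imputed_value = meta$imputed_value)
}
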