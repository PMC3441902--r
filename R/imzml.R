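#' @include grid-model.R
NULL

## Continuous-mode imzML 1.1 support. imzML is an mzML dialect whose binary
## arrays live in an external ".ibd" file (16-byte UUID header, then raw
## little-endian arrays referenced by byte offset from the XML). Only the
## continuous layout (one shared m/z array, one intensity array per spot) is
## supported; processed-mode files have per-spot m/z axes and are rejected.
## Coordinates: imzML positions are 1-based; SpectrumGrid uses 0-based, so
## the reader subtracts 1 and the writer adds 1.

.IMS_CONTINUOUS <- "IMS:1000030"
.IMS_PROCESSED <- "IMS:1000031"
.IMS_POS_X <- "IMS:1000050"
.IMS_POS_Y <- "IMS:1000051"
.IMS_EXT_OFFSET <- "IMS:1000102"
.IMS_EXT_LENGTH <- "IMS:1000103"
.MS_MZ_ARRAY <- "MS:1000514"
.MS_INT_ARRAY <- "MS:1000515"
.MS_F64 <- "MS:1000523"
.MS_F32 <- "MS:1000521"
.MS_I64 <- "MS:1000522"
.MS_I32 <- "MS:1000519"
.MS_NO_COMPRESSION <- "MS:1000576"

.ibdPath <- function(path) {
    cand <- c(sub("\\.[^.]*$", ".ibd", path),
              sub("\\.[^.]*$", ".IBD", path))
    hit <- cand[file.exists(cand)]
    if (!length(hit))
        stop("companion binary file not found next to ", path,
             " (expected ", cand[1L], ")")
    hit[1L]
}

.accessions <- function(node) {
    xml2::xml_attr(xml2::xml_find_all(node, "./cvParam"), "accession")
}

.cvValue <- function(node, accession) {
    p <- xml2::xml_find_first(node,
        sprintf("./cvParam[@accession='%s']", accession))
    if (inherits(p, "xml_missing")) NA_character_ else xml2::xml_attr(p, "value")
}

.readImzML <- function(path) {
    doc <- xml2::read_xml(path)
    xml2::xml_ns_strip(doc)
    fc <- xml2::xml_find_first(doc, ".//fileDescription/fileContent")
    acc <- if (inherits(fc, "xml_missing")) character() else .accessions(fc)
    if (.IMS_PROCESSED %in% acc)
        stop("processed-mode imzML (per-spot m/z axes) is not supported; ",
             "convert to continuous mode or bin explicitly before import")
    if (!(.IMS_CONTINUOUS %in% acc))
        stop("imzML file does not declare the continuous layout ",
             "(accession ", .IMS_CONTINUOUS, "); refusing to guess")

    ## referenceable param groups carry the per-array-type metadata
    groups <- xml2::xml_find_all(doc, ".//referenceableParamGroup")
    gacc <- lapply(groups, .accessions)
    names(gacc) <- xml2::xml_attr(groups, "id")

    spectra <- xml2::xml_find_all(doc, ".//run//spectrum")
    if (!length(spectra))
        stop("no spectra found in ", path)

    ibd <- .ibdPath(path)
    con <- file(ibd, "rb")
    on.exit(close(con))

    n <- length(spectra)
    xs <- integer(n); ys <- integer(n)
    mz <- NULL
    intens <- NULL

    for (i in seq_len(n)) {
        sp <- spectra[[i]]
        scan <- xml2::xml_find_first(sp, ".//scan")
        px <- .cvValue(scan, .IMS_POS_X)
        py <- .cvValue(scan, .IMS_POS_Y)
        if (is.na(px) || is.na(py))
            stop("spectrum ", i, " lacks grid position cvParams")
        xs[i] <- as.integer(px); ys[i] <- as.integer(py)
        arrays <- xml2::xml_find_all(sp, ".//binaryDataArray")
        for (arr in arrays) {
            aacc <- .accessions(arr)
            ref <- xml2::xml_attr(
                xml2::xml_find_first(arr, "./referenceableParamGroupRef"),
                "ref")
            if (!is.na(ref) && ref %in% names(gacc))
                aacc <- c(aacc, gacc[[ref]])
            isMz <- .MS_MZ_ARRAY %in% aacc
            isInt <- .MS_INT_ARRAY %in% aacc
            if (!isMz && !isInt) next
            if (!(.MS_NO_COMPRESSION %in% aacc))
                stop("compressed binary arrays are not supported")
            what <- if (.MS_F64 %in% aacc || .MS_I64 %in% aacc)
                list(type = "double", size = 8L)
            else if (.MS_F32 %in% aacc || .MS_I32 %in% aacc)
                list(type = if (.MS_F32 %in% aacc) "double" else "integer",
                     size = 4L)
            else stop("binary array lacks a recognised data-type cvParam")
            off <- as.numeric(.cvValue(arr, .IMS_EXT_OFFSET))
            len <- as.numeric(.cvValue(arr, .IMS_EXT_LENGTH))
            if (is.na(off) || is.na(len))
                stop("binary array lacks external offset/length cvParams")
            if (isMz && !is.null(mz)) next   # continuous: shared m/z axis
            seek(con, where = off, origin = "start")
            vals <- readBin(con, what = what$type, n = len,
                            size = what$size, endian = "little")
            if (length(vals) != len)
                stop("truncated ibd file: wanted ", len, " values at offset ",
                     off)
            if (isMz) {
                mz <- as.numeric(vals)
            } else {
                if (is.null(intens))
                    intens <- matrix(NA_real_, n, len)
                if (ncol(intens) != len)
                    stop("intensity array length varies between spectra; ",
                         "file is not truly continuous")
                intens[i, ] <- as.numeric(vals)
            }
        }
    }
    if (is.null(mz)) stop("no m/z array found")
    if (is.null(intens)) stop("no intensity arrays found")
    if (length(mz) != ncol(intens))
        stop("m/z axis length (", length(mz),
             ") does not match intensity array length (", ncol(intens), ")")
    if (length(mz) > 1L && any(diff(mz) <= 0))
        stop("m/z axis must be strictly increasing")
    SpectrumGrid(intens, coords = data.frame(col = xs - 1L, row = ys - 1L),
                 mz = mz)
}

#' Write a grid as continuous-mode imzML
#'
#' Emits a minimal continuous-mode imzML file plus its `.ibd` binary
#' companion (64-bit little-endian floats, no compression): the shared m/z
#' axis once, then one intensity array per spot. Positions are written
#' 1-based per the imzML convention.
#'
#' @param x a `SpectrumGrid`.
#' @param path output `.imzML` path; the `.ibd` file is written next to it.
#' @return `path`, invisibly.
#' @seealso [readSpectrumGrid()]
#' @export
writeImzML <- function(x, path) {
    stopifnot(is(x, "SpectrumGrid"))
    ibd <- sub("\\.[^.]*$", ".ibd", path)
    if (ibd == path) ibd <- paste0(path, ".ibd")
    m <- spectraMatrix(x)
    cc <- gridCoords(x)
    mz <- mzAxis(x)
    n <- nrow(m); p <- ncol(m)

    uuid <- as.raw(c(0x69, 0x6d, 0x73, 0x6d, 0x6e, 0x66, 0x00, 0x00,
                     rep(0x00, 8)))
    con <- file(ibd, "wb")
    writeBin(uuid, con)
    writeBin(as.numeric(mz), con, size = 8L, endian = "little")
    for (i in seq_len(n))
        writeBin(as.numeric(m[i, ]), con, size = 8L, endian = "little")
    close(con)
    uuidStr <- paste0("{", paste0(format(as.hexmode(as.integer(uuid)),
                                         width = 2), collapse = ""), "}")

    mzOffset <- 16
    intOffset0 <- 16 + 8 * p
    specXml <- vapply(seq_len(n), function(i) paste0(
        '      <spectrum id="spectrum=', i, '" index="', i - 1L,
        '" defaultArrayLength="', p, '">\n',
        '        <scanList count="1">\n          <scan>\n',
        '            <cvParam cvRef="IMS" accession="IMS:1000050" name="position x" value="',
        cc$col[i] + 1L, '"/>\n',
        '            <cvParam cvRef="IMS" accession="IMS:1000051" name="position y" value="',
        cc$row[i] + 1L, '"/>\n',
        '          </scan>\n        </scanList>\n',
        '        <binaryDataArrayList count="2">\n',
        '          <binaryDataArray encodedLength="0">\n',
        '            <referenceableParamGroupRef ref="mzArray"/>\n',
        '            <cvParam cvRef="IMS" accession="IMS:1000103" name="external array length" value="', p, '"/>\n',
        '            <cvParam cvRef="IMS" accession="IMS:1000102" name="external offset" value="', mzOffset, '"/>\n',
        '            <cvParam cvRef="IMS" accession="IMS:1000104" name="external encoded length" value="', 8 * p, '"/>\n',
        '            <binary/>\n          </binaryDataArray>\n',
        '          <binaryDataArray encodedLength="0">\n',
        '            <referenceableParamGroupRef ref="intensityArray"/>\n',
        '            <cvParam cvRef="IMS" accession="IMS:1000103" name="external array length" value="', p, '"/>\n',
        '            <cvParam cvRef="IMS" accession="IMS:1000102" name="external offset" value="',
        sprintf("%.0f", intOffset0 + (i - 1) * 8 * p), '"/>\n',
        '            <cvParam cvRef="IMS" accession="IMS:1000104" name="external encoded length" value="', 8 * p, '"/>\n',
        '            <binary/>\n          </binaryDataArray>\n',
        '        </binaryDataArrayList>\n      </spectrum>'),
        character(1L))

    xml <- paste0(
'<?xml version="1.0" encoding="UTF-8"?>\n',
'<mzML xmlns="http://psi.hupo.org/ms/mzml" version="1.1">\n',
'  <cvList count="3">\n',
'    <cv id="MS" fullName="Proteomics Standards Initiative Mass Spectrometry Ontology" URI="http://psidev.info/ms/mzML/psi-ms.obo"/>\n',
'    <cv id="UO" fullName="Unit Ontology" URI="http://obo.cvs.sourceforge.net/obo/obo/ontology/phenotype/unit.obo"/>\n',
'    <cv id="IMS" fullName="Imaging MS Ontology" URI="http://www.maldi-msi.org/download/imzml/imagingMS.obo"/>\n',
'  </cvList>\n',
'  <fileDescription>\n    <fileContent>\n',
'      <cvParam cvRef="MS" accession="MS:1000579" name="MS1 spectrum" value=""/>\n',
'      <cvParam cvRef="IMS" accession="IMS:1000030" name="continuous" value=""/>\n',
'      <cvParam cvRef="IMS" accession="IMS:1000080" name="universally unique identifier" value="', uuidStr, '"/>\n',
'    </fileContent>\n  </fileDescription>\n',
'  <referenceableParamGroupList count="2">\n',
'    <referenceableParamGroup id="mzArray">\n',
'      <cvParam cvRef="MS" accession="MS:1000514" name="m/z array" value="" unitCvRef="MS" unitAccession="MS:1000040" unitName="m/z"/>\n',
'      <cvParam cvRef="MS" accession="MS:1000523" name="64-bit float" value=""/>\n',
'      <cvParam cvRef="MS" accession="MS:1000576" name="no compression" value=""/>\n',
'      <cvParam cvRef="IMS" accession="IMS:1000101" name="external data" value="true"/>\n',
'    </referenceableParamGroup>\n',
'    <referenceableParamGroup id="intensityArray">\n',
'      <cvParam cvRef="MS" accession="MS:1000515" name="intensity array" value="" unitCvRef="MS" unitAccession="MS:1000131" unitName="number of detector counts"/>\n',
'      <cvParam cvRef="MS" accession="MS:1000523" name="64-bit float" value=""/>\n',
'      <cvParam cvRef="MS" accession="MS:1000576" name="no compression" value=""/>\n',
'      <cvParam cvRef="IMS" accession="IMS:1000101" name="external data" value="true"/>\n',
'    </referenceableParamGroup>\n',
'  </referenceableParamGroupList>\n',
'  <softwareList count="1">\n',
'    <software id="imsmnf" version="', as.character(utils::packageVersion("imsmnf")), '"/>\n',
'  </softwareList>\n',
'  <scanSettingsList count="1">\n',
'    <scanSettings id="scansettings1">\n',
'      <cvParam cvRef="IMS" accession="IMS:1000042" name="max count of pixels x" value="', max(cc$col) + 1L, '"/>\n',
'      <cvParam cvRef="IMS" accession="IMS:1000043" name="max count of pixels y" value="', max(cc$row) + 1L, '"/>\n',
'    </scanSettings>\n  </scanSettingsList>\n',
'  <instrumentConfigurationList count="1">\n',
'    <instrumentConfiguration id="IC1"/>\n',
'  </instrumentConfigurationList>\n',
'  <dataProcessingList count="1">\n',
'    <dataProcessing id="export">\n',
'      <processingMethod order="1" softwareRef="imsmnf">\n',
'        <cvParam cvRef="MS" accession="MS:1000544" name="Conversion to mzML" value=""/>\n',
'      </processingMethod>\n    </dataProcessing>\n  </dataProcessingList>\n',
'  <run id="run1" defaultInstrumentConfigurationRef="IC1">\n',
'    <spectrumList count="', n, '" defaultDataProcessingRef="export">\n',
paste(specXml, collapse = "\n"), '\n',
'    </spectrumList>\n  </run>\n</mzML>\n')
    writeLines(xml, path, sep = "", useBytes = TRUE)
    invisible(path)
}
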