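#' Functional classification of CLC proteins
#'
#' Turns motif and alignment evidence into the family's functional calls:
#' anion specificity from the second residue of the GxGxPE selectivity
#' filter (proline = nitrate, serine = chloride), transport mechanism from
#' the gating and proton glutamates (both present = anion/H+ antiporter,
#' exactly one = channel), CBS regulatory domain placement, and a
#' Table-style annotation report per protein.
#'
#' @name classify
NULL

#' Reference bundle for classification
#'
#' Loads the anchor reference (a CLC protein with known gating/proton
#' glutamate and filter coordinates), CBS reference segments and homolog
#' set from a directory containing `reference.fasta`, `anchors.json`,
#' `cbs.fasta` and `homologs.fasta`. The packaged default is a *synthetic*
#' bundle (files under `extdata/reference_synthetic/`, generated by the
#' package's own blueprint generator): real reference sequences (e.g.
#' EcCLC, AtCLCa-g) cannot be redistributed here but drop into the same
#' format.
#'
#' @param path bundle directory; default the packaged synthetic bundle.
#' @return list: `reference` (sequence string), `reference_id`, `anchors`
#'   (named integer vector `gating`, `proton`), `filter_start`,
#'   `filter_len`, `cbs` (named character vector), `homologs` (`clc_seqs`).
#' @export
reference_bundle <- function(path = NULL) {
  path <- path %||% system.file("extdata", "reference_synthetic",
                                package = "clcscan", mustWork = TRUE)
  meta <- jsonlite::read_json(file.path(path, "anchors.json"),
                              simplifyVector = TRUE)
  ref <- read_fasta(file.path(path, "reference.fasta"), "protein")
  cbs <- read_fasta(file.path(path, "cbs.fasta"), "protein")
  hom <- read_fasta(file.path(path, "homologs.fasta"), "protein")
  list(reference = ref$sequence[1], reference_id = ref$id[1],
       anchors = c(gating = as.integer(meta$gating),
                   proton = as.integer(meta$proton)),
       filter_start = as.integer(meta$filter_start),
       filter_len = as.integer(meta$filter_len %||% 6L),
       cbs = setNames(cbs$sequence, cbs$id),
       homologs = hom,
       synthetic = isTRUE(meta$synthetic))
}

#' Annotation thresholds and windows
#'
#' @param n_limit cytosolic N-terminal window for sorting signals when no
#'   topology is available (default 120 residues; flagged in reports).
#' @param tm_window,tm_threshold,tm_min_span hydropathy TM calling
#'   parameters (defaults 19 / 1.6 / 10).
#' @param cbs_min_identity,cbs_min_cols CBS hit acceptance: percent
#'   identity over at least this many aligned columns (defaults 50 / 40; 50 sits above the ~42 percent empirical null ceiling of same-composition shuffles).
#' @param phi hydrophobic class for YXXphi.
#' @param identity_mode denominator mode for [percent_identity()].
#' @return list of settings (class `clc_config`).
#' @export
annotate_config <- function(n_limit = 120L, tm_window = 19L,
                            tm_threshold = 1.6, tm_min_span = 10L,
                            cbs_min_identity = 50, cbs_min_cols = 40L,
                            phi = PHI_DEFAULT,
                            identity_mode = "endgap_excluded") {
  structure(list(n_limit = n_limit, tm_window = tm_window,
                 tm_threshold = tm_threshold, tm_min_span = tm_min_span,
                 cbs_min_identity = cbs_min_identity,
                 cbs_min_cols = cbs_min_cols, phi = phi,
                 identity_mode = identity_mode), class = "clc_config")
}

#' Extract the selectivity filter and call anion specificity
#'
#' Primary path: the first GxGxPE scan hit; its second residue sets the
#' specificity (P = nitrate, S = chloride, anything else = unknown).
#' Fallback: when no motif matches and a reference with known filter
#' coordinates is supplied, the region the global alignment maps onto the
#' reference filter is reported with specificity `"degenerate"`.
#'
#' @param seq protein sequence string.
#' @param reference optional reference protein string.
#' @param filter_start 1-based start of the filter on the reference.
#' @param filter_len filter length on the reference (default 6).
#' @return list: `filter_seq` (6-residue window), `filter_display`
#'   (Table-style 5-character string for motif hits, full mapped window
#'   when degenerate), `filter_start`, `residue2`, `specificity`.
#' @export
extract_selectivity_filter <- function(seq, reference = NULL,
                                       filter_start = NULL, filter_len = 6L) {
  hits <- scan_motif(seq, clc_motifs()$GxGxPE)
  if (nrow(hits)) {
    matched <- hits$matched[1]
    r2 <- substr(matched, 2, 2)
    spec <- if (r2 == "P") "nitrate" else if (r2 == "S") "chloride" else "unknown"
    return(list(filter_seq = matched,
                filter_display = substr(matched, 1, 5),
                filter_start = hits$start[1], residue2 = r2,
                specificity = spec))
  }
  if (!is.null(reference) && !is.null(filter_start)) {
    pos <- map_anchor_positions(seq, reference,
                                filter_start:(filter_start + filter_len - 1L))
    mapped <- pos[!is.na(pos)]
    if (length(mapped)) {
      fs <- chars_seq(seq_chars(seq)[mapped])
      return(list(filter_seq = fs, filter_display = fs,
                  filter_start = mapped[1],
                  residue2 = if (length(mapped) >= 2L)
                    substr(fs, 2, 2) else NA_character_,
                  specificity = "degenerate"))
    }
  }
  list(filter_seq = NA_character_, filter_display = NA_character_,
       filter_start = NA_integer_, residue2 = NA_character_,
       specificity = "unknown")
}

#' Gating/proton glutamate status via anchor mapping
#'
#' Maps the reference's gating and proton glutamate positions onto the
#' query by global alignment. A glutamate is "present" only when the
#' mapped query column carries exactly `E`; aspartate or any other residue
#' counts as absent (with the residue recorded), as does a deletion.
#'
#' @param seq query protein string.
#' @param reference anchor reference protein string.
#' @param anchors named integer vector `c(gating =, proton =)` of 1-based
#'   reference positions.
#' @return list with `gating` and `proton`, each
#'   `list(residue, position, present)`; positions in query numbering.
#' @export
glutamate_status <- function(seq, reference, anchors) {
  pos <- map_anchor_positions(seq, reference,
                              c(anchors[["gating"]], anchors[["proton"]]))
  one <- function(p) {
    if (is.na(p)) return(list(residue = NA_character_,
                              position = NA_integer_, present = FALSE))
    r <- substr(seq, p, p)
    list(residue = r, position = p, present = identical(r, "E"))
  }
  list(gating = one(pos[1]), proton = one(pos[2]))
}

#' Transport-mechanism call from the two-glutamate decision table
#'
#' Both glutamates present: anion/H+ antiporter. Exactly one: channel.
#' Neither: unknown. The table is total: every combination yields exactly
#' one call.
#'
#' @param status output of [glutamate_status()].
#' @return list: `mechanism` (`"antiporter"`, `"channel"`, `"unknown"`),
#'   `rationale`.
#' @export
call_transport_mechanism <- function(status) {
  g <- isTRUE(status$gating$present)
  p <- isTRUE(status$proton$present)
  if (g && p)
    list(mechanism = "antiporter",
         rationale = "gating and proton glutamates both present")
  else if (g || p)
    list(mechanism = "channel",
         rationale = paste("only the", if (g) "gating" else "proton",
                           "glutamate present"))
  else
    list(mechanism = "unknown", rationale = "neither key glutamate present")
}

#' Compose the Table-style function call
#'
#' @param specificity from [extract_selectivity_filter()].
#' @param mechanism from [call_transport_mechanism()].
#' @return list: `call` (printable string), `low_confidence`.
#' @export
function_call <- function(specificity, mechanism) {
  lc <- mechanism != "antiporter" ||
    !specificity %in% c("nitrate", "chloride")
  call <- switch(mechanism,
    antiporter = switch(specificity,
      nitrate = "NO3-/H+ exchange",
      chloride = "Cl-/H+ exchange",
      "anion/H+ exchange"),
    channel = "Cl- channel",
    "not determined")
  list(call = call, low_confidence = lc)
}

#' Locate CBS regulatory domains in the C-terminal half
#'
#' Each reference CBS segment is placed by best local alignment within the
#' C-terminal half of the query; a hit is reported when identity meets the
#' threshold over at least `min_cols` aligned columns.
#'
#' @param seq query protein string.
#' @param cbs_refs named character vector of reference segments
#'   (e.g. `CBS1`, `CBS2`).
#' @param min_identity,min_cols acceptance thresholds (defaults 50 percent
#'   over >= 40 columns).
#' @return data.frame `domain`, `start`, `end`, `identity` (query
#'   coordinates); zero rows when nothing qualifies.
#' @export
locate_cbs_domains <- function(seq, cbs_refs, min_identity = 50,
                               min_cols = 40L) {
  n <- nchar(seq)
  offset <- floor(n / 2)
  region <- substr(seq, offset + 1L, n)
  out <- list()
  for (dom in names(cbs_refs)) {
    la <- local_align(region, cbs_refs[[dom]])
    if (la$ncol >= min_cols && la$identity >= min_identity)
      out[[length(out) + 1L]] <- data.frame(
        domain = dom, start = la$start + offset, end = la$end + offset,
        identity = la$identity, stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(domain = character(0), start = integer(0),
                      end = integer(0), identity = numeric(0)))
  do.call(rbind, out)
}

not_determined <- function(reason) list(value = NA, reason = reason)

#' Full annotation report for one protein
#'
#' The machine twin of a family feature table: physicochemical summary,
#' selectivity filter and specificity, glutamate states, mechanism and
#' function call, CBS domains, sorting signals, best homolog with percent
#' identity, and transmembrane count. Sub-call failures become explicit
#' "not determined" fields with reasons; the call never aborts.
#'
#' @param seq protein sequence string.
#' @param id record identifier.
#' @param references a [reference_bundle()].
#' @param config an [annotate_config()].
#' @return A `clc_annotation` list.
#' @export
annotate_protein <- function(seq, id = "query",
                             references = reference_bundle(),
                             config = annotate_config()) {
  seq <- toupper(seq)
  rep <- list(id = id, length = nchar(seq))
  try_field <- function(expr) {
    tryCatch(expr, error = function(e) not_determined(conditionMessage(e)))
  }
  rep$mass_kda <- try_field(compute_mass(seq))
  rep$pi <- try_field(compute_pi(seq))
  rep$gravy <- try_field(compute_gravy(seq))
  rep$selectivity <- try_field(extract_selectivity_filter(
    seq, references$reference, references$filter_start,
    references$filter_len))
  rep$glutamates <- try_field(glutamate_status(
    seq, references$reference, references$anchors))
  rep$mechanism <- if (is.list(rep$glutamates) &&
                       !is.null(rep$glutamates$gating))
    call_transport_mechanism(rep$glutamates)
  else list(mechanism = "unknown", rationale = "glutamate status unavailable")
  spec <- if (!is.null(rep$selectivity$specificity))
    rep$selectivity$specificity else "unknown"
  rep$function_call <- function_call(spec, rep$mechanism$mechanism)
  rep$cbs <- try_field(locate_cbs_domains(
    seq, references$cbs, config$cbs_min_identity, config$cbs_min_cols))
  rep$sorting_signals <- try_field(find_sorting_signals(
    seq, n_limit = min(config$n_limit, nchar(seq)), phi = config$phi))
  rep$signal_window <- c(n_limit = config$n_limit,
                         note = "fixed terminal windows; no topology model")
  rep$tm <- try_field({
    prof <- hydropathy_profile(seq, config$tm_window)
    predict_tm_segments(prof, config$tm_threshold, config$tm_min_span)
  })
  rep$tm_count <- if (is.data.frame(rep$tm)) nrow(rep$tm) else NA_integer_
  rep$best_homolog <- try_field({
    ids <- references$homologs$id
    idty <- vapply(references$homologs$sequence, function(h) {
      percent_identity(global_align(seq, h), mode = config$identity_mode)
    }, numeric(1))
    list(id = ids[which.max(idty)], identity = max(idty))
  })
  structure(rep, class = "clc_annotation")
}

#' Annotate a whole sequence set
#'
#' @param seqs a protein `clc_seqs`.
#' @inheritParams annotate_protein
#' @return list of `clc_annotation`, one per record, named by id.
#' @export
annotate_set <- function(seqs, references = reference_bundle(),
                         config = annotate_config()) {
  stopifnot(inherits(seqs, "clc_seqs"))
  out <- lapply(seq_len(nrow(seqs)), function(i)
    annotate_protein(seqs$sequence[i], seqs$id[i], references, config))
  setNames(out, seqs$id)
}

fmt_or_nd <- function(x, fmt = "%s") {
  if (is.list(x) && !is.null(x$reason)) "not determined"
  else sprintf(fmt, x)
}

#' Render annotation reports as a Table-style TSV row set
#'
#' Column order follows the family feature table: id, length, mass (kDa,
#' one decimal), pI (two decimals), GRAVY (three decimals), best homolog
#' and identity, function, selectivity filter, Eg, Ep, then TM count, CBS
#' domains and signal count.
#'
#' @param reports list of `clc_annotation` (see [annotate_set()]).
#' @return data.frame, one row per protein.
#' @export
report_table <- function(reports) {
  rows <- lapply(reports, function(r) {
    glu_letter <- function(g) {
      if (is.list(g) && !is.null(g$residue) && !is.na(g$residue)) g$residue
      else "-"
    }
    data.frame(
      id = r$id,
      length = r$length,
      mass_kda = fmt_or_nd(r$mass_kda, "%.1f"),
      pI = fmt_or_nd(r$pi, "%.2f"),
      gravy = fmt_or_nd(r$gravy, "%.3f"),
      best_homolog = if (is.list(r$best_homolog) &&
                         !is.null(r$best_homolog$id))
        sprintf("%s (%.2f%% identity)", r$best_homolog$id,
                r$best_homolog$identity) else "not determined",
      func = paste0(r$function_call$call,
                    if (r$function_call$low_confidence) "?" else ""),
      filter = if (!is.null(r$selectivity$filter_display) &&
                   !is.na(r$selectivity$filter_display))
        r$selectivity$filter_display else "not determined",
      Eg = glu_letter(r$glutamates$gating),
      Ep = glu_letter(r$glutamates$proton),
      tm_count = r$tm_count,
      cbs = if (is.data.frame(r$cbs))
        paste(r$cbs$domain, collapse = ",") else "not determined",
      n_signals = if (is.data.frame(r$sorting_signals))
        nrow(r$sorting_signals) else NA_integer_,
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write annotation reports to TSV and JSON
#'
#' @param reports list of `clc_annotation`.
#' @param tsv,json output paths (either may be `NULL` to skip).
#' @return The report data.frame, invisibly.
#' @export
write_reports <- function(reports, tsv = NULL, json = NULL) {
  tab <- report_table(reports)
  if (!is.null(tsv))
    utils::write.table(tab, tsv, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  if (!is.null(json))
    jsonlite::write_json(reports, json, auto_unbox = TRUE, digits = NA,
                         force = TRUE, pretty = TRUE)
  invisible(tab)
}
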