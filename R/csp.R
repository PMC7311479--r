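#' Construct an amide peak list
#'
#' One 1H(15N) crosspeak per backbone amide from a 1H-15N HSQC spectrum.
#' Peaks without a residue assignment (e.g. from the unassigned variable
#' N-terminal region) may be included with `residue = NA`; they are carried
#' through matching summaries but excluded from per-residue profiles.
#'
#' @param residue integer residue numbers (unique among assigned peaks; NA
#'   allowed for unassigned peaks).
#' @param h_ppm amide proton chemical shifts (ppm).
#' @param n_ppm amide nitrogen chemical shifts (ppm).
#' @param label optional assignment labels (e.g. "G109N-H").
#' @param spectrum_label label for the spectrum/condition.
#' @return An object of class `peaklist` (a data frame with columns
#'   `residue`, `label`, `h_ppm`, `n_ppm`).
#' @export
peaklist <- function(residue, h_ppm, n_ppm, label = NULL,
                     spectrum_label = "spectrum") {
  n <- length(h_ppm)
  if (length(n_ppm) != n || length(residue) != n)
    stop("residue, h_ppm and n_ppm must have equal length")
  if (is.null(label)) label <- ifelse(is.na(residue), NA, paste0("R", residue))
  if (any(!is.finite(h_ppm)) || any(!is.finite(n_ppm)))
    stop("chemical shifts must be finite")
  assigned <- residue[!is.na(residue)]
  if (anyDuplicated(assigned)) {
    dup <- unique(assigned[duplicated(assigned)])
    stop("duplicate residue number(s) in peak list: ",
         paste(dup, collapse = ", "))
  }
  if (any(h_ppm < 5 | h_ppm > 12) || any(n_ppm < 100 | n_ppm > 135))
    warning("some shifts fall outside typical amide ranges ",
            "(1H 5-12 ppm, 15N 100-135 ppm)")
  out <- data.frame(residue = as.integer(residue), label = label,
                    h_ppm = h_ppm, n_ppm = n_ppm)
  attr(out, "spectrum_label") <- spectrum_label
  class(out) <- c("peaklist", "data.frame")
  out
}

# "G109N-H" / "K42NH" / "109N-H" -> 109; anything without digits -> NA
parse_assignment_residue <- function(label) {
  hit <- regexpr("[0-9]+", label)
  out <- rep(NA_integer_, length(label))
  out[hit > 0] <- as.integer(regmatches(label, hit))
  out
}

#' Read a peak list from Sparky-style or CSV text
#'
#' Sparky-style: whitespace-separated columns `Assignment  w1  w2` (the
#' nitrogen and proton dimensions are told apart by their ppm ranges, so
#' either column order is accepted). CSV: columns `residue`, `h_ppm`,
#' `n_ppm`. Assignment strings like "G109N-H" yield residue number 109;
#' assignments without a parseable residue number are kept as unassigned
#' peaks with a warning.
#'
#' @param path file path.
#' @param format `"auto"` (default), `"sparky"` or `"csv"`.
#' @param spectrum_label label for the spectrum.
#' @return A [peaklist()].
#' @export
read_peaklist <- function(path, format = c("auto", "sparky", "csv"),
                          spectrum_label = basename(path)) {
  format <- match.arg(format)
  first <- readLines(path, n = 1L)
  if (format == "auto")
    format <- if (grepl(",", first)) "csv" else "sparky"
  if (format == "csv") {
    df <- utils::read.csv(path)
    need <- c("residue", "h_ppm", "n_ppm")
    if (!all(need %in% names(df)))
      stop("expected CSV columns: ", paste(need, collapse = ", "))
    return(peaklist(df$residue, df$h_ppm, df$n_ppm,
                    label = if ("label" %in% names(df)) df$label else NULL,
                    spectrum_label = spectrum_label))
  }
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !grepl("^#", lines)]
  # drop a Sparky header line
  lines <- lines[!grepl("^Assignment", lines, ignore.case = TRUE)]
  parts <- strsplit(lines, "[[:space:]]+")
  ok <- lengths(parts) >= 3
  if (any(!ok)) warning(sum(!ok), " malformed line(s) skipped")
  parts <- parts[ok]
  lab <- vapply(parts, `[`, "", 1L)
  w1 <- as.numeric(vapply(parts, `[`, "", 2L))
  w2 <- as.numeric(vapply(parts, `[`, "", 3L))
  # nitrogen dimension is the one in the ~100-135 ppm range
  if (stats::median(w1) > stats::median(w2)) {
    n_ppm <- w1; h_ppm <- w2
  } else {
    n_ppm <- w2; h_ppm <- w1
  }
  residue <- parse_assignment_residue(lab)
  if (any(is.na(residue)))
    warning(sum(is.na(residue)),
            " assignment(s) without a residue number kept as unassigned")
  peaklist(residue, h_ppm, n_ppm, label = lab,
           spectrum_label = spectrum_label)
}

weighted_shift_dist <- function(dh, dn, nitrogen_weight = 0.14) {
  sqrt(dh^2 + (nitrogen_weight * dn)^2)
}

#' Match peaks between two conditions
#'
#' By default peaks are paired by residue number (assignments transferred
#' between conditions). With `by_assignment = FALSE` a greedy
#' minimum-distance pairing in weighted shift space
#' `d = sqrt(dH^2 + (w*dN)^2)` is used instead, accepting pairs with
#' `d <= cutoff`; each peak is used at most once. Unmatched peaks are
#' reported, never silently dropped.
#'
#' @param reference,modified [peaklist()] objects.
#' @param by_assignment pair by residue number (default TRUE).
#' @param cutoff weighted-ppm acceptance radius for distance matching.
#' @param nitrogen_weight weight on the 15N dimension, default 0.14.
#' @return A list with `pairs` (data frame: residue, shifts in both
#'   conditions, `dist`), `unmatched_reference`, `unmatched_modified`
#'   (row subsets of the inputs) and `n_unassigned` (peaks without residue
#'   numbers, excluded from residue pairing).
#' @export
match_peaks <- function(reference, modified, by_assignment = TRUE,
                        cutoff = 0.2, nitrogen_weight = 0.14) {
  if (nrow(reference) == 0 || nrow(modified) == 0)
    stop("peak lists must be non-empty")
  n_unassigned <- sum(is.na(reference$residue)) + sum(is.na(modified$residue))
  if (by_assignment) {
    r <- reference[!is.na(reference$residue), ]
    m <- modified[!is.na(modified$residue), ]
    common <- intersect(r$residue, m$residue)
    ri <- match(common, r$residue)
    mi <- match(common, m$residue)
    pairs <- data.frame(
      residue = common,
      h_ref = r$h_ppm[ri], n_ref = r$n_ppm[ri],
      h_mod = m$h_ppm[mi], n_mod = m$n_ppm[mi])
    pairs$dist <- weighted_shift_dist(pairs$h_mod - pairs$h_ref,
                                      pairs$n_mod - pairs$n_ref,
                                      nitrogen_weight)
    pairs <- pairs[order(pairs$residue), ]
    rownames(pairs) <- NULL
    um_ref <- reference[!(reference$residue %in% common) |
                          is.na(reference$residue), ]
    um_mod <- modified[!(modified$residue %in% common) |
                         is.na(modified$residue), ]
  } else {
    d <- outer(seq_len(nrow(reference)), seq_len(nrow(modified)),
               function(i, j) weighted_shift_dist(
                 modified$h_ppm[j] - reference$h_ppm[i],
                 modified$n_ppm[j] - reference$n_ppm[i],
                 nitrogen_weight))
    used_r <- logical(nrow(reference)); used_m <- logical(nrow(modified))
    idx <- list()
    repeat {
      k <- which.min(d)
      if (length(k) == 0 || !is.finite(d[k]) || d[k] > cutoff) break
      ij <- arrayInd(k, dim(d))
      idx[[length(idx) + 1L]] <- c(ij[1], ij[2], d[k])
      used_r[ij[1]] <- TRUE; used_m[ij[2]] <- TRUE
      d[ij[1], ] <- Inf; d[, ij[2]] <- Inf
    }
    if (length(idx)) {
      im <- do.call(rbind, idx)
      pairs <- data.frame(
        residue = reference$residue[im[, 1]],
        h_ref = reference$h_ppm[im[, 1]], n_ref = reference$n_ppm[im[, 1]],
        h_mod = modified$h_ppm[im[, 2]], n_mod = modified$n_ppm[im[, 2]],
        dist = im[, 3])
      pairs <- pairs[order(pairs$residue), ]
      rownames(pairs) <- NULL
    } else {
      pairs <- data.frame(residue = integer(), h_ref = numeric(),
                          n_ref = numeric(), h_mod = numeric(),
                          n_mod = numeric(), dist = numeric())
    }
    um_ref <- reference[!used_r, ]
    um_mod <- modified[!used_m, ]
  }
  list(pairs = pairs, unmatched_reference = um_ref,
       unmatched_modified = um_mod, n_unassigned = n_unassigned,
       nitrogen_weight = nitrogen_weight)
}

#' Per-residue weighted chemical-shift perturbations
#'
#' Total normalised 1H/15N CSP per residue:
#' `csp = sqrt(dH^2 + (w * dN)^2)` with nitrogen weight `w` (default 0.14,
#' the conventional scaling that puts amide 15N shift changes on the 1H
#' scale). Symmetric in the two conditions and invariant to a global
#' referencing offset applied to both.
#'
#' @param pairs result of [match_peaks()], or a data frame with columns
#'   `residue`, `h_ref`, `n_ref`, `h_mod`, `n_mod`.
#' @param nitrogen_weight 15N weight, > 0, default 0.14.
#' @return An object of class `csp_profile`: data frame with `residue`,
#'   `delta_h`, `delta_n`, `csp`; attributes `nitrogen_weight`, `matched`,
#'   `unmatched_reference`, `unmatched_modified`.
#' @export
compute_csp <- function(pairs, nitrogen_weight = 0.14) {
  if (nitrogen_weight <= 0) stop("nitrogen_weight must be positive")
  um_ref <- um_mod <- NULL
  if (is.list(pairs) && !is.null(pairs$pairs)) {
    um_ref <- pairs$unmatched_reference
    um_mod <- pairs$unmatched_modified
    pairs <- pairs$pairs
  }
  out <- data.frame(
    residue = pairs$residue,
    delta_h = pairs$h_mod - pairs$h_ref,
    delta_n = pairs$n_mod - pairs$n_ref)
  out$csp <- weighted_shift_dist(out$delta_h, out$delta_n, nitrogen_weight)
  out <- out[order(out$residue), ]
  rownames(out) <- NULL
  attr(out, "nitrogen_weight") <- nitrogen_weight
  attr(out, "matched") <- nrow(out)
  attr(out, "unmatched_reference") <-
    if (is.null(um_ref)) 0L else nrow(um_ref)
  attr(out, "unmatched_modified") <-
    if (is.null(um_mod)) 0L else nrow(um_mod)
  class(out) <- c("csp_profile", "data.frame")
  out
}

#' Significance threshold for a CSP profile
#'
#' Default (`"trimmed_sd"`): mean + 1 SD computed after iteratively
#' excluding values above mean + 3 SD until no value is excluded — the
#' standard convention for calling perturbed residues without letting the
#' perturbed sites themselves inflate the cutoff. `"fixed"` returns a
#' user-supplied value.
#'
#' @param profile a [compute_csp()] profile (or numeric csp vector).
#' @param method `"trimmed_sd"` or `"fixed"`.
#' @param value the threshold when `method = "fixed"`.
#' @return threshold in ppm.
#' @export
csp_threshold <- function(profile, method = c("trimmed_sd", "fixed"),
                          value = NULL) {
  method <- match.arg(method)
  if (method == "fixed") {
    if (is.null(value)) stop("supply `value` for the fixed method")
    return(value)
  }
  x <- if (is.data.frame(profile)) profile$csp else profile
  if (length(x) < 5)
    stop("need at least 5 csp values for the trimmed mean + SD threshold")
  keep <- x
  repeat {
    cut <- mean(keep) + 3 * stats::sd(keep)
    nxt <- keep[keep <= cut | is.na(cut)]
    if (length(nxt) == length(keep)) break
    keep <- nxt
  }
  s <- stats::sd(keep)
  if (is.na(s)) s <- 0
  mean(keep) + s
}

#' Find sequence clusters of perturbed residues
#'
#' Maximal runs of residues with `csp > threshold`, allowing up to `max_gap`
#' consecutive below-threshold or missing residues inside a run; runs whose
#' sequence span is shorter than `min_length` are discarded. Clusters are
#' returned ordered by start residue. Two such clusters (on the canonical
#' EF-hand entering helix and on the non-canonical EF-hand exiting helix /
#' SAM linker) are the hallmark pattern of S-nitrosylation-induced
#' perturbation of the STIM2 luminal domain.
#'
#' @param profile a `csp_profile`.
#' @param threshold ppm; default `csp_threshold(profile)`.
#' @param min_length minimum cluster span in residues, default 3.
#' @param max_gap maximum in-run gap (residues), default 1.
#' @return data frame of class `csp_clusters`: `start_residue`,
#'   `end_residue`, `n_above`, `mean_csp`, `max_csp` per cluster.
#' @export
detect_clusters <- function(profile, threshold = NULL, min_length = 3,
                            max_gap = 1) {
  if (is.null(threshold)) threshold <- csp_threshold(profile)
  if (threshold <= 0) stop("threshold must be positive")
  prof <- profile[order(profile$residue), ]
  above <- prof$residue[prof$csp > threshold]
  res <- data.frame(start_residue = integer(), end_residue = integer(),
                    n_above = integer(), mean_csp = numeric(),
                    max_csp = numeric())
  if (length(above) == 0) {
    class(res) <- c("csp_clusters", "data.frame")
    attr(res, "threshold") <- threshold
    return(res)
  }
  runs <- split(above, cumsum(c(1, diff(above) > max_gap + 1)))
  for (r in runs) {
    span <- r[length(r)] - r[1] + 1L
    if (span < min_length) next
    inside <- prof$csp[prof$residue >= r[1] & prof$residue <= r[length(r)]]
    res <- rbind(res, data.frame(
      start_residue = r[1], end_residue = r[length(r)],
      n_above = length(r), mean_csp = mean(inside), max_csp = max(inside)))
  }
  res <- res[order(res$start_residue), ]
  rownames(res) <- NULL
  attr(res, "threshold") <- threshold
  class(res) <- c("csp_clusters", "data.frame")
  res
}

#' Map a CSP profile onto a structure
#'
#' Writes (i) a per-residue TSV of csp values with an above-threshold flag
#' and (ii) a copy of the PDB file whose temperature-factor (B-factor)
#' column carries `100 * csp` (capped at 999.99; residues without a csp set
#' to 0), so any molecular viewer can colour the structure by perturbation.
#'
#' @param profile a `csp_profile`.
#' @param pdb_file path to a PDB-format coordinate file (e.g. the STIM2
#'   EF-SAM NMR structure 2L5Y).
#' @param chain chain identifier; default the first chain in the file.
#' @param out_pdb output path for the rewritten PDB.
#' @param out_tsv optional output path for the per-residue table.
#' @param threshold ppm; default `csp_threshold(profile)`.
#' @return Invisibly, a list with `table` (residue, csp, above_threshold,
#'   mapped), `not_mapped` (profile residues absent from the chain) and
#'   `out_pdb`.
#' @export
map_to_structure <- function(profile, pdb_file, chain = NULL,
                             out_pdb = tempfile(fileext = ".pdb"),
                             out_tsv = NULL, threshold = NULL) {
  if (is.null(threshold)) threshold <- csp_threshold(profile)
  pdb <- bio3d::read.pdb(pdb_file)
  atoms <- pdb$atom
  if (is.null(chain)) chain <- atoms$chain[1]
  sel <- atoms$chain %in% chain
  chain_res <- unique(atoms$resno[sel])
  overlap <- intersect(profile$residue, chain_res)
  if (length(overlap) == 0)
    stop("no residue-number overlap between profile (",
         min(profile$residue), "-", max(profile$residue),
         ") and chain ", chain, " (", min(chain_res), "-", max(chain_res), ")")
  b <- rep(0, nrow(atoms))
  for (i in seq_len(nrow(profile))) {
    hit <- sel & atoms$resno == profile$residue[i]
    if (any(hit)) b[hit] <- min(100 * profile$csp[i], 999.99)
  }
  bio3d::write.pdb(pdb, b = b, file = out_pdb)
  tab <- data.frame(residue = profile$residue, csp = profile$csp,
                    above_threshold = profile$csp > threshold,
                    mapped = profile$residue %in% chain_res)
  not_mapped <- profile$residue[!tab$mapped]
  if (!is.null(out_tsv))
    utils::write.table(tab, out_tsv, sep = "\t", row.names = FALSE,
                       quote = FALSE)
  invisible(list(table = tab, not_mapped = not_mapped, out_pdb = out_pdb,
                 threshold = threshold))
}
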