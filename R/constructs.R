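# Average residue masses (Da) for the 20 standard amino acids, plus one
# water per chain. These are the conventional average (not monoisotopic)
# values appropriate for linear-mode MALDI-TOF of ~18 kDa proteins.
AA_AVG_MASS <- c(
  G = 57.0519, A = 71.0788, S = 87.0782, P = 97.1167, V = 99.1326,
  T = 101.1051, C = 103.1388, L = 113.1594, I = 113.1594, N = 114.1038,
  D = 115.0886, Q = 128.1307, K = 128.1741, E = 129.1155, M = 131.1926,
  H = 137.1411, F = 147.1766, R = 156.1875, Y = 163.1760, W = 186.2132)
WATER_MASS <- 18.0153

#' Residue average-mass table
#'
#' @return Named numeric vector of average residue masses (Da); add
#'   18.0153 Da (one water) per chain for a protein mass.
#' @export
residue_masses <- function() AA_AVG_MASS

#' Protease recognition and cleavage rules
#'
#' TEV NIa protease cleaves ENLYFQ|G (after the Gln when followed by Gly);
#' thrombin cleaves LVPR|GS; HRV3C cleaves LEVLFQ|GP (the canonical site,
#' overridable). Patterns are perl regexes with a lookahead for the C-side
#' residue(s); `cut_after` is the offset of the cut within the matched
#' N-side motif.
#'
#' @return Named list of `list(pattern, cut_after, motif)` rules.
#' @export
protease_sites <- function() {
  list(
    TEV = list(pattern = "ENLYFQ(?=G)", cut_after = 6L, motif = "ENLYFQG"),
    thrombin = list(pattern = "LVPR(?=GS)", cut_after = 4L, motif = "LVPRGS"),
    HRV3C = list(pattern = "LEVLFQ(?=GP)", cut_after = 6L, motif = "LEVLFQGP")
  )
}

check_sequence <- function(sequence) {
  stopifnot(is.character(sequence), length(sequence) == 1)
  chars <- strsplit(toupper(sequence), "")[[1]]
  bad <- which(!chars %in% names(AA_AVG_MASS))
  if (length(bad) > 0)
    stop("non-standard residue '", chars[bad[1]], "' at position ", bad[1])
  paste(chars, collapse = "")
}

#' Digest a protein sequence with site-specific proteases
#'
#' All recognition sites of the selected proteases are cut simultaneously
#' and completely; fragments are returned in N-to-C order. A sequence
#' without any selected motif is returned unchanged (one fragment).
#'
#' @param sequence Amino-acid sequence (20 standard residues).
#' @param proteases Character vector among `names(protease_sites())`.
#' @param sites Rule list, by default [protease_sites()].
#' @return Character vector of fragment sequences, N-terminal first.
#' @export
digest <- function(sequence, proteases, sites = protease_sites()) {
  sequence <- check_sequence(sequence)
  unknown <- setdiff(proteases, names(sites))
  if (length(unknown) > 0) stop("unknown protease: ", paste(unknown, collapse = ", "))
  cuts <- integer(0)
  for (p in proteases) {
    rule <- sites[[p]]
    m <- gregexpr(rule$pattern, sequence, perl = TRUE)[[1]]
    if (m[1] != -1) cuts <- c(cuts, as.integer(m) + rule$cut_after - 1L)
  }
  cuts <- sort(unique(cuts))
  starts <- c(1L, cuts + 1L)
  ends <- c(cuts, nchar(sequence))
  substring(sequence, starts, ends)
}

#' Average molecular mass of a protein sequence
#'
#' Sum of average residue masses plus one water (18.0153 Da) per chain; no
#' post-translational modifications, initiator Met retained as written.
#'
#' @param sequence Amino-acid sequence.
#' @return Average mass in Da.
#' @export
average_mass <- function(sequence) {
  sequence <- check_sequence(sequence)
  sum(AA_AVG_MASS[strsplit(sequence, "")[[1]]]) + WATER_MASS
}

DOMAIN_KINDS <- c("RGG", "MBP", "SZ1", "SZ2", "cargo")

#' Fusion-protein construct specification
#'
#' Ordered domain architecture of an engineered fusion protein. Domains are
#' given N-to-C as a character vector mixing structural/functional kinds
#' (`RGG`, `MBP`, `SZ1`, `SZ2`, `cargo`) and protease cut sites (named by
#' their protease: `TEV`, `thrombin`, `HRV3C`). Optionally each domain
#' carries a sequence (cut sites default to their recognition motif), from
#' which fragment sequences and masses can be derived.
#'
#' @param name Construct name.
#' @param domains Character vector, e.g. `c("RGG", "TEV", "RGG")` for the
#'   TEV-cleavable tandem construct.
#' @param sequences Optional named or positional character vector of domain
#'   sequences (one per domain; `NA` allowed). Cut-site domains default to
#'   the protease recognition motif.
#' @return An object of class `construct_spec`.
#' @export
construct_spec <- function(name, domains, sequences = NULL) {
  sites <- protease_sites()
  kind <- ifelse(domains %in% names(sites), "cut_site", domains)
  if (!all(kind %in% c(DOMAIN_KINDS, "cut_site")))
    stop("unknown domain kind: ",
         paste(setdiff(kind, c(DOMAIN_KINDS, "cut_site")), collapse = ", "))
  protease <- ifelse(kind == "cut_site", domains, NA_character_)
  seqs <- rep(NA_character_, length(domains))
  if (!is.null(sequences)) {
    stopifnot(length(sequences) == length(domains))
    seqs <- as.character(sequences)
  }
  for (i in which(kind == "cut_site")) {
    if (is.na(seqs[i])) seqs[i] <- sites[[protease[i]]]$motif
    else if (!grepl(sites[[protease[i]]]$pattern, seqs[i], perl = TRUE))
      stop("cut-site domain ", i, " lacks the ", protease[i], " recognition motif")
  }
  structure(list(name = name,
                 domains = data.frame(kind = kind, protease = protease,
                                      sequence = seqs,
                                      stringsAsFactors = FALSE)),
            class = "construct_spec")
}

#' @export
print.construct_spec <- function(x, ...) {
  lbl <- ifelse(x$domains$kind == "cut_site",
                paste0("x(", x$domains$protease, ")"), x$domains$kind)
  cat(x$name, ":", paste(lbl, collapse = "-"), "\n")
  invisible(x)
}

#' Species census after protease digestion of a construct
#'
#' Cuts the construct at every declared cut site whose protease is selected
#' and reports, per resulting fragment (species), the RGG valency (count of
#' intact RGG domains), MBP presence, recruitment tags, and -- when every
#' domain sequence is known -- the fragment's average mass. A protease with
#' no matching cut site in the construct is a no-op.
#'
#' @param construct A [construct_spec()].
#' @param proteases Character vector of protease names applied (may be empty).
#' @return data.frame with one row per species: `fragment` (domain formula),
#'   `valency`, `has_MBP`, `tags` (comma-joined subset of SZ1/SZ2/cargo),
#'   `mass` (Da or NA), `sequence` (or NA).
#' @export
species_census <- function(construct, proteases = character()) {
  stopifnot(inherits(construct, "construct_spec"))
  unknown <- setdiff(proteases, names(protease_sites()))
  if (length(unknown) > 0) stop("unknown protease: ", paste(unknown, collapse = ", "))
  dm <- construct$domains
  cut_here <- dm$kind == "cut_site" & dm$protease %in% proteases
  # split the domain list at cut positions; the cut-site residues themselves
  # split at the protease's scissile bond (N-side stays left, C-side right)
  group <- cumsum(c(0L, head(cut_here, -1)))  # fragment index per domain
  have_seq <- !any(is.na(dm$sequence))
  sites <- protease_sites()
  out <- lapply(split(seq_len(nrow(dm)), group), function(ix) {
    sub <- dm[ix, , drop = FALSE]
    frag_parts <- ifelse(sub$kind == "cut_site",
                         paste0("x(", sub$protease, ")"), sub$kind)
    seq <- NA_character_
    if (have_seq) {
      pieces <- character(0)
      for (j in seq_len(nrow(sub))) {
        s <- sub$sequence[j]
        if (sub$kind[j] == "cut_site" && cut_here[ix[j]]) {
          # this (last-in-fragment) cut site contributes only its N-side
          ca <- sites[[sub$protease[j]]]$cut_after
          m <- regexpr(sites[[sub$protease[j]]]$pattern, s, perl = TRUE)
          s <- substring(s, 1, as.integer(m) + ca - 1L)
        }
        pieces <- c(pieces, s)
      }
      # a cut site terminating the previous fragment leaves its C-side here
      first <- ix[1]
      if (first > 1 && cut_here[first - 1]) {
        prev <- dm[first - 1, ]
        ca <- sites[[prev$protease]]$cut_after
        m <- regexpr(sites[[prev$protease]]$pattern, prev$sequence, perl = TRUE)
        pieces <- c(substring(prev$sequence, as.integer(m) + ca), pieces)
      }
      seq <- paste(pieces, collapse = "")
    }
    tags <- intersect(unique(sub$kind), c("SZ1", "SZ2", "cargo"))
    data.frame(fragment = paste(frag_parts, collapse = "-"),
               valency = sum(sub$kind == "RGG"),
               has_MBP = any(sub$kind == "MBP"),
               tags = paste(tags, collapse = ","),
               mass = if (have_seq) average_mass(seq) else NA_real_,
               sequence = seq,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Empirical phase and recruitment rule table
#'
#' Measured phase behavior of multivalent RGG constructs encoded as a lookup
#' table (these are empirical point estimates, not thermodynamic
#' predictions): transition temperature by RGG valency (~15 degC for single
#' RGG, ~40 for tandem, ~50 for triplet), an MBP solubilization override, and
#' enrichment-index classes for cargo recruitment.
#'
#' @param t_by_valency Named numeric vector: transition temperature (degC)
#'   per valency; must be strictly increasing with valency.
#' @param mbp_soluble Does an MBP tag keep a species soluble at any
#'   temperature?
#' @param recruitment Named numeric vector of expected enrichment indices by
#'   cargo class.
#' @return An object of class `phase_rule_table`.
#' @export
phase_rule_table <- function(t_by_valency = c("1" = 15, "2" = 40, "3" = 50),
                             mbp_soluble = TRUE,
                             recruitment = c(excluded = 0.8, single_RGG = 4,
                                             SZ = 20, double_RGG = 27)) {
  v <- as.integer(names(t_by_valency))
  stopifnot(!any(is.na(v)), all(diff(t_by_valency[order(v)]) > 0))
  structure(list(t_by_valency = t_by_valency, mbp_soluble = mbp_soluble,
                 recruitment = recruitment),
            class = "phase_rule_table")
}

#' Predict phase state of a digested species mixture
#'
#' A species phase-separates iff it carries no MBP tag, has valency >= 1,
#' and the temperature is below the rule table's transition temperature for
#' its valency. The system is turbid iff any species phase-separates; the
#' governing threshold is the maximum applicable transition temperature
#' among phase-competent species.
#'
#' @param species [species_census()] output.
#' @param temperature Query temperature, degC.
#' @param rules A [phase_rule_table()].
#' @return List with `state` (`"turbid"` or `"soluble"`) and `threshold`
#'   (degC; the governing transition temperature, NA when no species is
#'   phase-competent).
#' @export
predict_phase_state <- function(species, temperature, rules = phase_rule_table()) {
  stopifnot(inherits(rules, "phase_rule_table"))
  competent <- species$valency >= 1 & !(species$has_MBP & rules$mbp_soluble)
  if (!any(competent)) return(list(state = "soluble", threshold = NA_real_))
  vals <- species$valency[competent]
  missing <- setdiff(as.character(vals), names(rules$t_by_valency))
  if (length(missing) > 0)
    stop("rule table has no transition temperature for valency ",
         paste(missing, collapse = ", "))
  tts <- rules$t_by_valency[as.character(vals)]
  threshold <- max(tts)
  list(state = if (temperature < threshold) "turbid" else "soluble",
       threshold = unname(threshold))
}

#' Predict recruitment of a cargo construct into scaffold droplets
#'
#' Rule-based expected enrichment of a tagged cargo in droplets formed by a
#' scaffold construct, optionally after protease treatment (which may sever
#' the cargo from its recruitment tag, revoking recruitment, and may also
#' dissolve the scaffold droplets). Classes: cargo fused to two RGG domains
#' (strong, EI ~27); SZ2-tagged cargo with an SZ1-bearing scaffold
#' (strong, EI ~20); one RGG domain (weak, EI ~4); otherwise excluded
#' (EI < 1).
#'
#' @param scaffold,cargo [construct_spec()] objects.
#' @param rules A [phase_rule_table()].
#' @param temperature Query temperature, degC.
#' @param proteases Proteases applied to the system (affect both constructs).
#' @return List with `class`, `ei`, `released` (recruitment revoked by the
#'   protease treatment relative to no treatment), `droplets_intact`
#'   (scaffold still phase-separated after treatment).
#' @export
predict_recruitment <- function(scaffold, cargo, rules = phase_rule_table(),
                                temperature = 25, proteases = character()) {
  sc0 <- predict_phase_state(species_census(scaffold), temperature, rules)
  if (sc0$state != "turbid")
    stop("scaffold does not phase separate at ", temperature, " degC: no droplets")
  sc1 <- predict_phase_state(species_census(scaffold, proteases), temperature, rules)
  scaffold_tags <- scaffold$domains$kind
  classify <- function(prot) {
    cs <- species_census(cargo, prot)
    carg <- cs[grepl("cargo", cs$tags), , drop = FALSE]
    if (nrow(carg) == 0) return(list(class = "excluded", ei = rules$recruitment[["excluded"]]))
    carg <- carg[1, ]
    tags <- strsplit(carg$tags, ",")[[1]]
    if (carg$valency >= 2)
      list(class = "double_RGG", ei = rules$recruitment[["double_RGG"]])
    else if ("SZ2" %in% tags && "SZ1" %in% scaffold_tags)
      list(class = "SZ", ei = rules$recruitment[["SZ"]])
    else if (carg$valency == 1)
      list(class = "single_RGG", ei = rules$recruitment[["single_RGG"]])
    else
      list(class = "excluded", ei = rules$recruitment[["excluded"]])
  }
  before <- classify(character())
  after <- classify(proteases)
  list(class = after$class, ei = unname(after$ei),
       released = before$class != "excluded" && after$class == "excluded",
       droplets_intact = sc1$state == "turbid")
}

#' Read protein sequences from a FASTA file
#'
#' Thin wrapper over `Biostrings::readAAStringSet` returning a plain named
#' character vector.
#'
#' @param path FASTA file.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  if (requireNamespace("Biostrings", quietly = TRUE)) {
    x <- Biostrings::readAAStringSet(path)
    setNames(as.character(x), sub("\\s.*$", "", names(x)))
  } else {
    lines <- readLines(path)
    hdr <- grepl("^>", lines)
    id <- cumsum(hdr)
    seqs <- vapply(split(lines[!hdr], id[!hdr]), paste, "", collapse = "")
    setNames(toupper(gsub("\\s", "", seqs)),
             sub("^>(\\S+).*$", "\\1", lines[hdr]))
  }
}
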