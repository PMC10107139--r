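#' Define a genome map
#'
#' A genome map lists the chromosome-level sequences to simulate or scan,
#' their physical lengths, and the genetic map length per chromosome. The
#' crossing design assumes exactly one crossover per female meiosis per
#' chromosome, i.e. a map length of 50 cM, which is the default.
#'
#' @param chromosomes Character vector of unique chromosome names.
#' @param lengths Numeric vector of chromosome lengths in bp (all > 0).
#' @param map_length_cM Genetic map length per chromosome in centimorgans.
#'   Only 50 (one obligate crossover per tetrad) is used by the simulator;
#'   the value is stored for provenance.
#'
#' @return An object of class `genome_map`: a tibble with columns `chrom`
#'   and `length`, with the map length as an attribute.
#' @examples
#' genome_map(c("X", "4"), c(30.6e6, 26e6))
#' @export
genome_map <- function(chromosomes, lengths, map_length_cM = 50) {
  chromosomes <- as.character(chromosomes)
  lengths <- as.numeric(lengths)
  if (length(chromosomes) != length(lengths)) {
    stop("`chromosomes` and `lengths` must have equal length")
  }
  if (anyDuplicated(chromosomes)) stop("chromosome names must be unique")
  if (any(!is.finite(lengths)) || any(lengths <= 0)) {
    stop("chromosome lengths must be positive")
  }
  g <- tibble::tibble(chrom = chromosomes, length = lengths)
  attr(g, "map_length_cM") <- map_length_cM
  class(g) <- c("genome_map", class(g))
  g
}

#' Default genome map for the montana-group crossing design
#'
#' Approximate chromosome-level scaffold sizes for the six chromosome units
#' analysed (X, 2L, 2R, 3, 4, 5; the dot chromosome is not assembled).
#' Chromosome-wise mean hybrid index does not depend on physical length under
#' the uniform-map model, so these sizes matter only for window statistics.
#'
#' @return A [genome_map()].
#' @export
default_genome <- function() {
  genome_map(
    chromosomes = c("X", "2L", "2R", "3", "4", "5"),
    lengths = c(30.6e6, 11.0e6, 16.0e6, 24.0e6, 26.0e6, 26.0e6)
  )
}

chrom_length <- function(genome, chrom) {
  i <- match(chrom, genome$chrom)
  if (is.na(i)) stop("unknown chromosome: ", chrom)
  genome$length[i]
}

#' Load inversion intervals from a BED file
#'
#' Reads fixed-inversion breakpoint intervals (BED, 0-based half-open) and
#' validates them against a genome map. Overlapping inversions on one
#' chromosome (the X carries several) are retained as given; downstream code
#' works with their union.
#'
#' @param path Path to a BED file with at least 3 columns; the optional name
#'   column is kept as `species_label` when present.
#' @param genome A [genome_map()]; every record must reference one of its
#'   chromosomes and lie within the chromosome length.
#'
#' @return A tibble with columns `chrom`, `start`, `end` (0-based half-open)
#'   and `species_label` (NA when the BED has no name column).
#' @export
load_inversions <- function(path, genome) {
  gr <- rtracklayer::import(path, format = "BED")
  if (length(gr) == 0L) {
    return(tibble::tibble(
      chrom = character(0), start = numeric(0), end = numeric(0),
      species_label = character(0)
    ))
  }
  inv <- tibble::tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = as.numeric(BiocGenerics::start(gr)) - 1,  # back to 0-based
    end = as.numeric(BiocGenerics::end(gr)),
    species_label = if (!is.null(gr$name)) as.character(gr$name) else
      NA_character_
  )
  validate_inversions(inv, genome)
  inv
}

#' Validate an inversion table against a genome map
#'
#' @param inversions Tibble with `chrom`, `start`, `end` (0-based half-open).
#' @param genome A [genome_map()].
#' @return The validated table, invisibly.
#' @export
validate_inversions <- function(inversions, genome) {
  for (i in seq_len(nrow(inversions))) {
    ch <- inversions$chrom[i]
    if (!ch %in% genome$chrom) {
      stop(sprintf("inversion record %d: unknown chromosome '%s'", i, ch))
    }
    L <- chrom_length(genome, ch)
    s <- inversions$start[i]; e <- inversions$end[i]
    if (!(s >= 0 && s < e && e <= L)) {
      stop(sprintf(
        "inversion record %d (%s:%g-%g): interval out of range for length %g",
        i, ch, s, e, L
      ))
    }
  }
  invisible(inversions)
}

#' Merged inversion union for one chromosome
#'
#' Overlapping inversions are collapsed with [IRanges::reduce()] so the
#' inverted "part" of a chromosome is treated as one region for crossover
#' suppression and incompatibility-locus placement.
#'
#' @param inversions Inversion tibble (see [load_inversions()]); may be NULL.
#' @param chrom Chromosome name.
#' @return Two-column matrix of merged (start, end) intervals, possibly empty.
#' @export
inversion_union <- function(inversions, chrom) {
  if (is.null(inversions) || nrow(inversions) == 0L) return(iv_empty())
  inv <- inversions[inversions$chrom == chrom, , drop = FALSE]
  if (nrow(inv) == 0L) return(iv_empty())
  # IRanges is integer-based; inversions are bp coordinates so this is exact
  ir <- IRanges::reduce(IRanges::IRanges(
    start = as.integer(inv$start) + 1L, end = as.integer(inv$end)
  ))
  cbind(as.numeric(BiocGenerics::start(ir)) - 1, as.numeric(BiocGenerics::end(ir)))
}

#' Construct a haplotype of ancestry tracts
#'
#' A haplotype is one chromosome copy encoded as ordered ancestry tracts
#' (0-based half-open) that tile `[0, L)`; adjacent tracts carry different
#' ancestries ("mon" or "fla").
#'
#' @param starts,ends Numeric tract bounds.
#' @param ancestry Character vector of tract ancestries, one of `"mon"`,
#'   `"fla"`.
#' @param L Chromosome length; the tracts must tile `[0, L)` exactly.
#' @return A `haplotype` object (list with `s`, `e`, `a`, `L`).
#' @export
haplotype <- function(starts, ends, ancestry, L) {
  h <- structure(
    list(s = as.numeric(starts), e = as.numeric(ends),
         a = as.character(ancestry), L = as.numeric(L)),
    class = "haplotype"
  )
  validate_haplotype(h)
  h
}

#' @noRd
validate_haplotype <- function(h) {
  n <- length(h$s)
  if (n == 0L) stop("haplotype has no tracts")
  if (length(h$e) != n || length(h$a) != n) stop("ragged tract vectors")
  if (h$s[1L] != 0) stop("tracts must start at 0")
  if (h$e[n] != h$L) stop("tracts must end at chromosome length")
  if (any(h$e <= h$s)) stop("empty or inverted tract")
  if (n > 1L) {
    if (any(h$s[-1L] != h$e[-n])) stop("tracts must be contiguous")
    if (any(h$a[-1L] == h$a[-n])) stop("adjacent tracts share ancestry")
  }
  if (!all(h$a %in% c("mon", "fla"))) stop("ancestry must be 'mon' or 'fla'")
  invisible(h)
}

# single-ancestry haplotype
pure_haplotype <- function(ancestry, L) {
  structure(list(s = 0, e = L, a = ancestry, L = L), class = "haplotype")
}

# merged intervals carrying `anc` ancestry (tracts already merged by
# construction: adjacent tracts differ, so just subset)
hap_tracts_of <- function(h, anc) {
  i <- h$a == anc
  if (!any(i)) return(iv_empty())
  cbind(h$s[i], h$e[i])
}

hap_ancestry_at <- function(h, x) {
  i <- findInterval(x, h$s)
  h$a[i]
}

hap_donor_length <- function(h, donor) {
  i <- h$a == donor
  if (!any(i)) return(0)
  sum(h$e[i] - h$s[i])
}

#' Construct a diploid individual
#'
#' An individual holds, per chromosome, an ordered (maternal, paternal) pair
#' of haplotypes. All simulated hybrids are female; in any backcross
#' individual the paternal copy is pure recipient-species ancestry because
#' backcrosses always use pure males.
#'
#' @param haplopairs Named list (by chromosome) of `list(maternal =, paternal =)`
#'   [haplotype()] pairs.
#' @return An `individual` object.
#' @export
individual <- function(haplopairs) {
  structure(list(chroms = haplopairs), class = "individual")
}

#' Donor-ancestry fraction of an individual on one chromosome
#'
#' The hybrid index of a single individual on a chromosome: total donor tract
#' length across both haplotypes divided by twice the chromosome length. An
#' F1 female is 0.5 everywhere; backcross females are at most 0.5.
#'
#' @param ind An [individual()].
#' @param donor Donor ancestry label ("mon" or "fla").
#' @param chrom Chromosome name.
#' @return Fraction in `[0, 1]`.
#' @export
donor_fraction <- function(ind, donor, chrom) {
  hp <- ind$chroms[[chrom]]
  if (is.null(hp)) stop("unknown chromosome: ", chrom)
  L <- hp$maternal$L
  (hap_donor_length(hp$maternal, donor) +
     hap_donor_length(hp$paternal, donor)) / (2 * L)
}

#' Pedigree configuration of the crossing experiment
#'
#' Encodes the conditioning of the simulation: how many F1 mothers found a
#' backcross direction, how many BC1 daughters each F1 mother contributes,
#' and how many BC2 daughters each BC1 mother contributes to the sequenced
#' pool of 82 females.
#'
#' @param direction `"to_mon"` (recipient is D. montana) or `"to_fla"`.
#' @param bc1_per_f1 Integer vector: BC1 daughter count per F1 mother.
#' @param bc2_per_bc1 Integer vector: BC2 daughter count per BC1 mother; its
#'   length must equal `sum(bc1_per_f1)` and its sum the pool size.
#' @param pool_size Number of BC2 females sequenced (default 82).
#' @return A `pedigree_config` object.
#' @export
pedigree_config <- function(direction = c("to_mon", "to_fla"),
                            bc1_per_f1, bc2_per_bc1, pool_size = 82L) {
  direction <- match.arg(direction)
  bc1_per_f1 <- as.integer(bc1_per_f1)
  bc2_per_bc1 <- as.integer(bc2_per_bc1)
  if (any(bc1_per_f1 < 0L) || any(bc2_per_bc1 < 0L)) {
    stop("pedigree counts must be >= 0")
  }
  if (length(bc2_per_bc1) != sum(bc1_per_f1)) {
    stop("length(bc2_per_bc1) must equal sum(bc1_per_f1)")
  }
  if (sum(bc2_per_bc1) != pool_size) {
    stop("sum(bc2_per_bc1) must equal pool_size")
  }
  structure(
    list(direction = direction, n_f1 = length(bc1_per_f1),
         bc1_per_f1 = bc1_per_f1, bc2_per_bc1 = bc2_per_bc1,
         pool_size = as.integer(pool_size)),
    class = "pedigree_config"
  )
}

# split n items over k bins as evenly as possible
even_split <- function(n, k) {
  base <- n %/% k
  extra <- n %% k
  c(rep(base + 1L, extra), rep(base, k - extra))
}

#' Default pedigree for a backcross direction
#'
#' The experiment used 4 F1 mothers, 14 BC1 females and 82 pooled BC2
#' females towards D. montana, and 3 F1 mothers, 22 BC1 females and 82 BC2
#' females towards D. flavomontana. Per-mother contributions are split as
#' evenly as possible (the neutral default; override with
#' [pedigree_config()] when the realised contributions are known).
#'
#' @param direction `"to_mon"` or `"to_fla"`.
#' @return A [pedigree_config()].
#' @export
default_pedigree <- function(direction = c("to_mon", "to_fla")) {
  direction <- match.arg(direction)
  if (direction == "to_mon") {
    n_f1 <- 4L; n_bc1 <- 14L
  } else {
    n_f1 <- 3L; n_bc1 <- 22L
  }
  pedigree_config(
    direction = direction,
    bc1_per_f1 = even_split(n_bc1, n_f1),
    bc2_per_bc1 = even_split(82L, n_bc1),
    pool_size = 82L
  )
}

#' Donor and recipient species labels for a cross direction
#'
#' @param direction `"to_mon"` or `"to_fla"`; backcrossing *to* a species
#'   makes it the recipient and the other species the donor.
#' @return Named list with `donor` and `recipient`.
#' @export
direction_labels <- function(direction = c("to_mon", "to_fla")) {
  direction <- match.arg(direction)
  if (direction == "to_mon") {
    list(donor = "fla", recipient = "mon")
  } else {
    list(donor = "mon", recipient = "fla")
  }
}

#' Read a genome map or pedigree from a YAML/JSON config file
#'
#' The genome config carries `chromosomes` (name/length pairs) and optional
#' `map_length_cM`; the pedigree config carries `direction`, `bc1_per_f1`,
#' `bc2_per_bc1` and optional `pool_size`.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A [genome_map()] or [pedigree_config()].
#' @export
read_genome_config <- function(path) {
  cfg <- read_config_file(path)
  chroms <- vapply(cfg$chromosomes, function(x) as.character(x$name), "")
  lens <- vapply(cfg$chromosomes, function(x) as.numeric(x$length), 0)
  map_cm <- if (!is.null(cfg$map_length_cM)) cfg$map_length_cM else 50
  genome_map(chroms, lens, map_length_cM = map_cm)
}

#' @rdname read_genome_config
#' @export
read_pedigree_config <- function(path) {
  cfg <- read_config_file(path)
  pedigree_config(
    direction = cfg$direction,
    bc1_per_f1 = unlist(cfg$bc1_per_f1),
    bc2_per_bc1 = unlist(cfg$bc2_per_bc1),
    pool_size = if (!is.null(cfg$pool_size)) cfg$pool_size else 82L
  )
}

read_config_file <- function(path) {
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = FALSE)
  }
}
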