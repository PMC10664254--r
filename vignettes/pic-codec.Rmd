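---
title: "Image-centric compression of atomic point clouds: the method behind picr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Image-centric compression of atomic point clouds: the method behind picr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(picr)
```

## The idea

The primary payload of a PDB or mmCIF file is a point cloud: one Cartesian
coordinate triple per atom, in Angstrom, one ASCII record per atom. The
listing order of those records is an artifact of sequential file formats —
nothing about the molecule depends on it. Ordinary practice (gzip over the
coordinate text, or over an integer-packed binary rendering of it) spends
bits preserving that arbitrary order and cannot reorder atoms for
compressibility.

`picr` takes the opposite route: it treats the cloud as a cloud. Atoms are
re-expressed in spherical coordinates about their global centroid,
quantized to one decimal, and *positionally* encoded into an 8-bit
greyscale image — two of the three coordinates become the pixel position,
the third is written into pixel intensity bits at that position. The image
is then handed to PNG, a mature lossless compressor that is very good at
the long zero runs and local structure such images have. Decompression
scans the image back into records, restores the original atom order from a
stored permutation, and re-renders the original file byte-identically
outside the coordinate fields.

## The forward transform

1. **Centering.** The global centroid $\mu$ of all $n$ coordinates is
   computed and subtracted. This minimizes the radial spread and hence the
   image width; $\mu$ is stored in the archive sidecar (3 doubles).
2. **Spherical conversion.** Each centred point becomes $(r, \phi,
   \theta)$: $r$ the Euclidean norm, $\phi$ the azimuth in $[0, 360)$
   degrees measured counter-clockwise from $+x$, $\theta$ the polar angle
   in $[0, 180]$ degrees measured from $+z$. The payload range of the
   packed record (an 11-bit field holding $10\theta \le 1800$) forces the
   polar reading of "elevation"; the azimuth carries the wider range
   because it is positionally encoded, not stored in bits.
3. **Quantization** — the sole lossy step. Every component is rounded to
   one decimal (0.1 Angstrom / 0.1 degree) and kept as an integer number
   of tenths. Since each coordinate component moves by at most 0.05 in $r$
   and 0.05 degree in each angle, every reconstructed point lies within
   0.2 Angstrom per Cartesian component, i.e. inside a Euclidean ball of
   radius $0.2\sqrt{3}$ Angstrom, for radii up to 200 Angstrom — ample for
   experimental coordinates whose positional uncertainty exceeds 0.2
   Angstrom anyway.

Three conventions are pinned here because the printed rules leave them
open, and reproducibility of RMSD values depends on them: ties round
*away from zero* (ordinary decimal rounding); an azimuth that rounds to
exactly 360.0 wraps to 0 (same direction); a point exactly at the centroid
takes $(0, 0, 0)$, any angle being valid at $r = 0$.

## Mapping into the image

With $\varepsilon$ pixels per azimuth degree, a quantized atom targets
image position $(x, y) = (10r, \varepsilon\phi)$: column $x$ is the radius
in tenths, and $y$ — generally fractional — addresses a *bit* of the
column, viewing each column of the 8-bit image as a bit string of length
$8 \cdot 360\varepsilon = 2880\varepsilon$ read most-significant-bit
first. Legal $\varepsilon$ values satisfy $\varepsilon \ge 1.25$ with
$0.8\varepsilon$ and $360\varepsilon$ integers, so every atom lands on an
integer bit index $b = 0.8\varepsilon \cdot (10\phi)$ and every tenth of a
degree owns $m = 0.8\varepsilon$ consecutive bits (its *azimuth bin*). The
image is nominally $10r^* \times 360\varepsilon$ for maximal radius $r^*$;
the realized canvas has $10r^* + 1$ columns so that column 0 exists, a
distinction cropping erases. The default $\varepsilon = 2.5$ (7200-bit
columns) is the setting under which the compressor performs best in
benchmarks; 1.25 shrinks images but multiplies collisions, 5 and 10 do
the reverse.

### Records

Each atom is stored as a self-delimiting record: a start bit `1`, a
pointer flag, an optional pointer of $\lceil\log_2 2880\varepsilon\rceil$
bits, and the 11-bit big-endian payload $10\theta$. Records are 13 bits
without pointer, 13 plus the pointer width with one. The flag alone
determines the length, which is what makes the decoder's scan unambiguous:
unwritten bits are 0, so a cursor walking a column advances by one on a 0
bit and by the record length after parsing a record.

### Collisions

When the target bits are already taken, candidates $b = (b_{\text{target}}
+ i) \bmod 2880\varepsilon$, $i = 0, 1, 2, \dots$ are scanned (the target
itself is candidate $i = 0$). A candidate still inside the atom's azimuth
bin takes a pointer-free record; any other candidate must carry a pointer
so the decoder can recover the intended azimuth. A candidate is accepted
iff the whole record — at the length that candidate implies — fits above
the column bottom (no record wraps around the image edge) and covers only
unwritten bits. The stored pointer is $p = (b^* - b') \bmod
2880\varepsilon$ where $b' = b_{\text{target}} + 0.8\varepsilon - 1$ is
the last bit of the intended bin; the modulus keeps $p$ positive when the
scan wraps past the column bottom, extending the printed non-wrapping rule
$p = 8(y^* - y') > 0$. The decoder inverts this as $\phi_{\text{decideg}}
= \lfloor ((b^* - p) \bmod 2880\varepsilon) / 0.8\varepsilon \rfloor$,
with $p = 0$ for pointer-free records.

If an entire column offers no slot, the atom moves to the next canvas, and
a fresh full-size canvas is opened when every existing one refuses —
canvases are retried in index order for every atom, so early images keep
filling. Atoms with identical quantized triples each get their own record;
the atom count is conserved exactly.

### Order restoration

Atoms are encoded in file order, but the decoder meets records in scan
order (image, then column, then bit). The archive stores the permutation
from scan order back to the original file index (4 bytes per atom in the
sidecar), so decompression is exact on ordering. This is the minimal
realization of keeping "reordering metadata"; discarding it would shrink
archives further at the cost of order.

### Cropping and PNG

Each canvas is cropped of its all-black margins; the top and left offsets
are the two per-image parameters stored for reversal (bottom and right
follow from the known full dimensions). The cropped rasters are PNG-
encoded: greyscale, bit depth 8, non-interlaced, via libpng. PNG is
lossless, so this layer is exactly bit-neutral — the tests assert decoded
rasters are pixel-identical — and only the compressed size depends on it.

## The gzip baseline

The comparison scheme renders the same information sequentially: each
coordinate is multiplied by 10 and rounded (same tie rule), delta-encoded
per axis in file order, zigzag-mapped and packed as LEB128 varints, then
gzipped at level 9. The reference size for *all* compression ratios —
PIC's and gzip's — is the rounded-coordinates text file ("-12.3 4.5 0.0"
lines), so both methods are compared at equal precision. The variable-
length binary layout behind the published baseline is not fully specified;
delta+zigzag+varint is used here as a representative member of that
family, so baseline sizes are indicative rather than byte-exact.
Kilobytes mean 1000 bytes throughout.

## The synthetic generator

All tests run without downloads, on seeded clouds from three generators:

- `uniform_ball` — points uniform in a ball. Its file order is spatially
  uncorrelated, which emulates the order-artifact property of real
  multi-chain and multi-model files; this is the regime where the image
  route beats sequential delta coding once clouds are large.
- `chain_walk` — a persistent random walk with 1.5 Angstrom steps
  (roughly a bond length), reflected inward at the ball boundary. It
  reproduces protein-like *local* density and is the baseline's best
  case: consecutive deltas are tiny, so gzip compresses it exceptionally
  well. Reporting both regimes brackets real structures.
- `duplicate_heavy` — a uniform cloud in which 20 percent of points are
  exact copies of earlier points, forcing the pointer and overflow-image
  machinery that real clouds exercise only rarely.

What the generator does *not* emulate: residue-level chemistry, secondary
structure, crystallographic symmetry, B-factor/occupancy statistics, or
the exact delta distribution of deposited files. Passing tests therefore
demonstrate codec *correctness* (exact round trips, bounds, conservation)
on clouds spanning the relevant density regimes, and *qualitative*
compression behaviour; they do not reproduce any particular deposited
entry's sizes.

## Numerical and design choices

- **Rounding ties** away from zero, implemented as
  $\operatorname{sign}(x)\lfloor 10|x| + 0.5\rfloor$ — affects only
  measure-zero ties but is pinned for reproducibility.
- **Availability length** during the slot scan is the *full* record
  length (prefix + optional pointer + payload), decided per candidate by
  whether that candidate sits in the no-pointer bin; anything shorter
  would let records overlap.
- **Decoder cursor semantics** (0 bit advances by one; records always
  start with 1) are implied by the self-delimiting record design rather
  than printed; the instrumented-encoder test pins them by requiring the
  scan to recover the exact write log.
- **Degenerate inputs**: a single atom is its own centroid, giving
  $r^* = 0$, a one-column canvas and a single 13-bit record; empty clouds
  are rejected.
- **Archive sidecar** is little-endian binary: magic, version,
  $m = 0.8\varepsilon$ as one byte, $\mu$, $r^*$, image count, per-image
  crop offsets, atom count, the permutation, and a gzip member holding
  the structure file with coordinate fields masked plus the per-atom
  field template — sufficient for byte-identical reconstruction outside
  coordinates. Serializing $m$ rather than $\varepsilon$ makes the two
  printed integrality constraints hold by construction.
- **Problem sizes in the suite**: the round-trip grid runs clouds up to
  50,000 atoms across all three modes, seeds 1–3 and
  $\varepsilon \in \{1.25, 2.5, 5\}$; the instrumented-log equivalence
  runs at 1,000 atoms; the benchmark script at 100,000 atoms. These sizes
  exercise multi-image overflow and dense-column scanning while keeping
  the default suite in the tens of seconds.

## A worked example

```{r}
pts <- generate_cloud(5000, r_max = 50, mode = "uniform_ball", seed = 1)
archive <- pic_encode(pts, codec_config(2.5))
archive
decoded <- pic_decode(archive)
rmsd(pts, decoded)
```

The reconstruction error sits near 0.04 Angstrom RMSD — the quantization
floor — and the quantized round trip is exact:

```{r}
q <- quantize_spherical(cart_to_spherical(sweep(pts, 2, centroid(pts))))
identical(unname(pic_decode(archive, quantized = TRUE)), unname(q))
```

## Limitations

- The codec is a *coordinate* compressor; non-coordinate metadata passes
  through gzipped but uncompetitively — pairing with a dedicated metadata
  compressor is out of scope.
- $\varepsilon$ is global and static; per-structure tuning is future
  work.
- Compression is only worthwhile for large clouds: below roughly 20,000
  atoms the image overhead dominates and the sequential baseline wins.
- Coordinates beyond about 200 Angstrom from the centroid weaken the
  per-component 0.2 Angstrom bound, since angular quantization error
  grows linearly with radius.
- mmCIF support assumes plain whitespace-separated `_atom_site` rows
  (the universal layout for coordinate loops); quoted or multi-line
  values in those rows are rejected rather than guessed at.
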