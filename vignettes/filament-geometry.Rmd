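---
title: "Modelling conventions: filament DNA geometry, relaxation and metrics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling conventions: filament DNA geometry, relaxation and metrics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(filamentforge)
```

This vignette records the modelling conventions behind `filamentforge`: how
nucleotides are reduced to pseudo-atoms, how the filament-bound DNA strands
are parameterized, how the spring network relaxes an assembly, and how every
reported observable is defined. All numeric defaults live in
`fil_defaults()` and can be overridden from a text file with
`read_fil_config()`.

## Reduced-atom representation

Each nucleotide is five pseudo-atoms:

| atom | meaning | placement |
|------|---------|-----------|
| `P` | phosphate | on the strand's helical track, radius $r_P$ |
| `C1'` | sugar anchor | radius $r_P - 1.7$ Å, azimuthally offset from P |
| `N9`/`N1` | glycosidic nitrogen (purine/pyrimidine) | 1.5 Å from C1′ along the base direction |
| `CEN` | base centroid | 3.5 Å from C1′ along the base direction |
| `O3'` | bridging oxygen | 1.6 Å from the *next* residue's P, on the segment toward this residue's C1′ |

The base direction $\hat b$ points from C1′ toward where the base's
Watson–Crick partner would sit; builders aim it at the actual partner when
one exists (`aim_bases_at()`), and at the strand's virtual partner track
otherwise.

### The azimuthal P→C1′ offset is derived, not fixed

The P–C1′ virtual bond has one ideal length, `p_c1_bond = 4.0` Å, at every
radius. With C1′ on a cylinder 1.7 Å inside the P cylinder, the azimuthal
offset that closes a 4.0 Å bond follows from the law of cosines in the
cross-sectional plane (ignoring the small axial component):

$$\cos\Delta\phi = \frac{r_P^2 + r_{C1'}^2 - b^2}{2\, r_P\, r_{C1'}},
\qquad b = 4.0\ \text{Å}.$$

`c1_az_offset_at(r_p, cfg)` evaluates this: 26.0° at $r_P = 9$ Å, 24.6° at
the B-form radius 9.4 Å, 19.0° at 12 Å and 15.0° at 15 Å. The offset is
applied against the strand's winding sense, so the P–C1′ geometry is at its
rest length by construction at any radius — which is what lets relaxation
leave built models essentially unmoved.

### O3′ placement and exact screw continuity

`O3'` of residue $i$ sits 1.6 Å from $P_{i+1}$ along the direction toward
$C1'_i$. For the last residue of a strand the "next P" is extrapolated by
one pattern step, so a fragment replicated by the filament screw
(`replicate_along_screw()`) is *exactly* continuous: `close_backbone()` on
screw-replicated fragments converges with zero phosphate drift.

## Strand parameterizations

B-form DNA (`build_bdna()`): 3.38 Å rise, 36° twist, P radius 9.4 Å,
antiparallel complement with C1′–C1′ pair span 10.4 Å.

Filament DNA (`build_filament_strand()`) follows the triplet pattern — two
intra-triplet steps of 3.6 Å / 25°, then one inter-triplet step of
8.1 Å / 10° — giving means of exactly 5.1 Å and 20° per step (1.509× the
B-form rise). One triplet corresponds to one protein subunit: three steps
sum to 15.3 Å and 60°, the filament screw (6 subunits per turn).

In the synaptic model (`build_synaptic_model()`) the three strands run on
coaxial cylinders:

| strand | chain | radius | role |
|--------|-------|--------|------|
| initiating | `I` | 9 Å | resident single strand in site I |
| complementary | `C` | 12 Å | duplex strand facing the initiating strand |
| outgoing | `O` | 15 Å | duplex strand facing away |

The complementary strand is antiparallel to the initiating strand and phased
90° from it; the outgoing strand is placed so its bases face the
complementary strand's across the duplex. The C1′–C1′ span of both the
C–O duplex and any attempted C–I pair is the same 10.4 Å chord; on a
cylinder of C1′ radius $r$ a chord of length $s$ subtends
$2\,\delta = 2\arcsin(s / 2r)$, which fixes each partner's azimuth.

### B-form tails and the junction

6-bp B-form tails attach to the outgoing/complementary duplex ends, bent by
`bend_angle = 90°` about an axis perpendicular to both helix axes. The
remaining degree of freedom — the spin of the tail about its own helix
axis — carries no information, so `place_tail()` picks, on a 30° grid, the
spin that maximizes the minimum distance between tail atoms and
already-placed atoms (the attaching residue excluded). This is deterministic
and keeps the tails clash-free, which matters because a clashed tail would
be pushed away during relaxation and corrupt the junction angle.

Because only the complementary strand is covalently continuous through each
junction, the outgoing chain has genuine backbone interruptions there (its
O3′…P distances across the junction are >20 Å).

## The duplet flip

`flip_duplet(structure, t)` moves the 5′-most two bases of complementary
triplet $t$ (pattern levels $3t-1, 3t$) from the site-II track onto the
site-I pairing position: each flipped C1′ is placed at radius
$9 - 1.7 = 7.3$ Å, azimuthally $2\arcsin(10.4 / 14.6)$ ahead of its
initiating partner's C1′, with P at 9 Å using the derived offset, and the
base re-aimed at the partner. The triplet's 3′ base is not moved — the
request is refused — reflecting the steric block by the protein's L2 loop.
The outgoing strand and all other residues are untouched.

## Protein anchors and salt bridges

Anchor sets are point templates replicated along the filament screw, one
copy per subunit: the site-II cluster (R226, R227, R243, K245), the
C-terminal-domain lysine patch (K280/K282/K286/K302) at larger radius, and
the L2 loops. `salt_bridge_map()` reports every phosphate within
`salt_bridge_cutoff = 5` Å of an anchor point. In the default model each
bound triplet contributes its two outgoing duplet phosphates to the
arginines and a complementary phosphate to K245 — a contact that is lost
when that triplet's duplet flips.

## Spring-network relaxation

`build_network()` turns a structure into harmonic terms
$E = \sum k (r - r_0)^2$:

- bonds: P–C1′ (rest 4.0 Å), C1′–N (1.5 Å), N–CEN (2.0 Å), O3′–P (1.6 Å),
  and C1′–O3′ at its as-built length (it varies legitimately with the step
  type);
- **strand breaks**: an inter-residue O3′–P pair further apart than
  `break_gap = 5` Å at build time is a real interruption (the outgoing
  chain at the tail junctions) and gets no bond;
- repulsion: soft $k(r_{\min} - r)^2$ below `r_min = 2.5` Å between atom
  pairs that are not bonded and not in the same or consecutive residues of
  one chain (the 1-2/1-3 covalent neighbourhood is excluded);
- anchors: phosphates currently within the salt-bridge cutoff of an anchor
  set are restrained to their positions.

`minimize()` is gradient descent with monotone backtracking line search;
the analytic gradient is verified against numeric differentiation in the
tests. Because built models are at rest, relaxing the default assembly
moves atoms by only ~0.05 Å RMSD and the junctions settle at 90.6°/89.2°.

`close_backbone()` relaxes fragment junctions onto 1.6 Å O3′–P bonds while
anchoring all phosphates; `radial_pull()` drags selected phosphates to a
target radius while bonds preserve the local screw (within 1% in the
tests).

## Metrics

All metrics are rigid-motion invariant (tested over random rotations and
translations):

- **axis**: explicit argument > stored metadata axis (transformed along
  with the coordinates) > inferred via `infer_axis()`, a screw fit between
  period-shifted copies of the strand.
- **rise/twist** (`step_parameters()`): per step, the axial projection of
  the P→P displacement and the signed angle between the radial components
  about the axis. `step_summary()` averages over whole triplets only.
- **extension factor**: mean rise / 3.38 Å.
- **D1/θ1** (`basepair_metrics()`): C1′(I)–C1′(C) distance, and the angle
  at the complementary C1′ between the directions to the initiating C1′ and
  to its own base nitrogen, both projected onto the plane perpendicular to
  the local complementary-strand tangent (the base-flipping plane).
  Classification thresholds are *calibrated*, not hard-coded: the paired
  template comes from `make_postsynaptic_reference()`, the unflipped
  template from a site-II stub, cached per configuration hash.
- **junction angle**: each tagged segment's helix axis is fitted
  independently and oriented along its residue order; the angle between the
  two axes is reported.
- **registration** (`registration_check()`): initiating and complementary
  site-II residues are expressed in cylindrical coordinates about the
  filament axis; after removing the constant axial and azimuthal offsets
  (medians), each triplet must agree within half an intra-step
  (`reg_axial_halfwidth = 2.55` Å, `reg_az_halfwidth = 10°`). The large
  *inter*-triplet P–P spacing is part of the pattern and is exempt.

## Scenarios, decoys and problem sizes

`scenario_spec()` fixes triplet count (1–5), tail lengths, bend angle,
noise σ, seed and decoy mode; `make_scenario()` is bitwise reproducible and
leaves the global RNG untouched. Decoys each violate exactly one
expectation: `wrong_twist` (uniform 30° steps), `misregistered`
(complementary pattern shifted one level), `unkinked` (0° bend).

Typical sizes: the default model is 42 nucleotides / 210 pseudo-atoms; a
full pipeline run (`run_scenario()`), including relaxation and all metrics,
takes ~2 s; the whole test suite runs in well under a minute.
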