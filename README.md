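# lesionsurf

Lesion-aware cortical surface volumetrics in R.

## The problem

Surface-based cortical volumetry (as produced by FreeSurfer-style
pipelines) models the cortex as two triangulated meshes — the pial and
gray–white surfaces — with a 1:1 vertex pairing whose separation is the
cortical thickness. The volume of a region is computed as

```
V = t̄ · A
```

where `t̄` is the mean regional thickness and `A` the regional surface
area. Focal cortical lesions (e.g. chronic post-traumatic
encephalomalacia) break the assumptions behind surface reconstruction:
the reconstructed surface passes through destroyed tissue, and any
thickness measured there is meaningless. Patients with such lesions are
therefore routinely excluded from volumetric studies.

`lesionsurf` implements a lesion *correction* approach instead: a rater
outlines the inaccurate surface patch (anchor points → closed path on the
mesh edge graph → flood fill), the labelled vertices are excluded from
the regional statistics, and volumes are recomputed on the remaining,
trustworthy cortex. On top of the corrected statistics, the package
quantifies how lesions are distributed across a 7-network functional
parcellation: lesion counts per network, percent of each network's
surface area overlapped by lesions, pre-/post-correction network volumes
and their percent change, and a group-level per-vertex lesion frequency
map. Scan-quality and reliability statistics used to vet inputs are
included: SNR within the white-matter mask, CNR as the mean of the WM–GM
and GM–CSF contrasts, ABC/2 lesion volumetry, and the intraclass
correlation coefficient (ICC(2,1)/ICC(3,1)) with F-based confidence
intervals.

Everything is testable offline: a deterministic synthetic-subject
generator produces spherical "cortices" with smooth thickness fields,
contiguous 7-network parcellations and planted lesions of known area
fraction, plus voxel phantoms with known tissue statistics, all with
exact recorded ground truth.

The package reads and writes the FreeSurfer file formats involved —
binary triangle surfaces, per-vertex `curv` scalars, ASCII labels, and
binary annotations with colortables — bit-exactly and interoperably
(verified against nibabel). Vertex indices are 0-based everywhere,
matching the on-disk label format.

## Worked example

Simulate a subject with a lesion covering 10% of the left limbic
network and 5% of the right default-mode network, then correct it:

```r
library(lesionsurf)

subj_dir <- tempfile("subject")
out_dir  <- tempfile("corrected")

cmd_simulate(42, subj_dir, lesion_specs = list(
  list(network = "Limbic",      fraction = 0.10, hemi = "lh"),
  list(network = "DefaultMode", fraction = 0.05, hemi = "rh")))
cmd_correct(subj_dir, out_dir)

rep <- read.delim(file.path(out_dir, "overlap_report.tsv"))
subset(rep, is_lesioned)
```

```
   network hemisphere n_lesions_in_network pct_surface_area_affected pre_volume_ml post_volume_ml pct_volume_change
    Limbic         lh                    1                     10.14        32.165         31.259            -2.899
DefaultMode        rh                    1                      5.10        31.998         31.552            -1.414
```

The planted 10% and 5% area fractions are recovered up to the
vertex-quantization of the lesion growth (10.14% and 5.10%). Volume
change is smaller in magnitude than area change because the simulated
lesions are thinned: the excluded vertices carried below-average
thickness, so removing them removes less than a proportional share of
volume. `out_dir` also contains per-hemisphere `all-lesions` overlays
(label + curv indicator) and pre/post stats tables
(`lh.stats.pre.tsv`, `lh.stats.post.tsv`, ...).

The same workflow is available from a shell via the installed
`lesionsurf` script (`simulate`, `label`, `correct`, `qc`, `groupmap`
subcommands); `label` turns an anchors file plus a seed vertex into the
next `lesion-NN.label` for the hemisphere, mirroring interactive
outline-and-fill labeling.

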