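# Bundled HGF signaling example (synthetic reconstruction)

These files encode the package's worked example: hepatocyte growth factor
(HGF) stimulated MAPK and PI3K signaling in primary hepatocytes, with a
core model of the main activation routes and 17 literature candidate
crosstalk/feedback mechanisms.

**Provenance.** All files are a *reconstruction assembled for this
package* (hence the `synthetic_` prefix): the species list, the core
routes, the candidate mechanisms and the discretized perturbation
responses were transcribed from published descriptions of this signaling
system, not from machine-readable supplementary material. Where the
published account states structural facts (17 candidate mechanisms; a
29-reaction core model; selected building blocks of four or five
candidate edges; a combined reference model of eight mechanisms including
the negative Akt->Raf1 crosstalk), the reconstruction honors them; where
it does not determine the content (exact rate-law table rows, the full
discretization figure, fitted parameter values), the files contain
choices made once for this package. The parameter table
`synthetic_hgf_params.csv` is entirely synthetic: values were chosen by
kinetic role (activations ~1/min, basal deactivations ~0.3/min,
candidate reactions ~0.3, receptor synthesis/turnover slow) to give
qualitatively sensible transient receptor and sustained downstream
dynamics. Quantities computed from these parameters (inhibitor screens,
crosstalk fluxes) therefore characterize the reconstruction, not the
original study.

## Files

- `synthetic_hgf_species.csv` — species (active forms; HGF is the
  stimulus input, PDK1 a constitutively active constant).
- `synthetic_hgf_edges.csv` — signed edge list; empty `mechanism` = core
  model, otherwise the candidate mechanism id (M01..M17).
- `synthetic_hgf_mechanisms.csv` — mechanism labels.
- `synthetic_hgf_observations.csv` — discretized early/late responses of
  the measured phosphoproteins for each condition pair (control vs the
  same condition plus one or two inhibitors). Entries are
  `increase`/`decrease`/`not_conclusive`; a conclusive `no_change` never
  occurs, matching the published account of the data.
- `synthetic_hgf_annotations.csv` — ODE translation category for every
  positive candidate edge that can appear after compression
  (`independent` parallel activation vs `modulating` an existing core
  activation).
- `synthetic_hgf_params.csv` — synthetic reference parameter table
  (log10 values) covering the reference combined model.

Load everything through `hybridnet::hgf_fixture()`.
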