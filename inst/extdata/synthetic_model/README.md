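# Synthetic model transcription

These three TSV files define the reaction network the package simulates:

* `species_synthetic.tsv` — species symbols, display names, elementary
  protein moiety content, submodel tag (`base_extrinsic` / `pc_pathway`).
* `reactions_synthetic.tsv` — mass-action reactions; `<->` rows are expanded
  into an association/dissociation pair on load.
* `rates_synthetic.tsv` — rate constants in per-second /
  per-nanomolar-per-second units, with row-level provenance notes.

The files are **synthetic** in the following sense.  The base extrinsic
cascade (R01–R31, k1–k42) is a transcription of the Hockin, Jones, Everse &
Mann (2002) *J Biol Chem* 277:18322 model of tissue-factor-initiated thrombin
generation, which is reproduced in many published works.  The protein C
pathway module (R32–R45, kpc01–kpc21) implements the processes this model
lineage describes — thrombomodulin binding to thrombin and meizothrombin,
protein C activation by both Tm complexes, antithrombin inhibition of the
thrombin–soluble-Tm complex, and APC inactivation of fVa (sequential
Arg506/Arg306 cleavages) and fVIIIa — with rate constants chosen at
literature-plausible orders of magnitude by the package authors, not copied
from any published table.  Treat the PC-module constants as a modeling
stand-in, adequate for the qualitative negative feedback they encode.

Moiety bookkeeping: the fVIIIa A2-domain fragment carries its own moiety
label (`VIII2`) so that the 1→2 split `VIIIa -> VIIIa1=L + VIIIa2` conserves
integer moiety counts; all 12 moiety vectors are conserved by every reaction.
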