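# Toy fixture (`make_toy_fixture()`)

A fully deterministic, hand-specified instance used to trace every pipeline
stage by hand. All values are generated in code from closed-form patterns;
no random numbers are involved. The dataset is synthetic by construction.

## Construction

Samples: `d01`-`d10` (disease), `c01`-`c10` (control); sample index
j = 1..20. Gene rows:

| gene | pattern | role |
|------|---------|------|
| g01 | 3·[disease] + 0.5·sin(j)  | DE, in P1 |
| g02 | 3·[disease] + 0.5·cos(j)  | DE, in P1 |
| g03 | 3·[disease] + 0.5·sin(2j) | DE, shared P1∩P2 |
| g04 | 0.5·cos(2j)  | not DE, shared P1∩P2 |
| g05 | 0.5·sin(3j)  | P2 |
| g06 | 0.5·cos(3j)  | not DE, shared P2∩P3 |
| g07 | 0.5·sin(4j)  | P3 |
| g08 | 0.5·cos(4j)  | P3 |
| g09 | 0.5·sin(5j)  | P4 |
| g10 | 0.5·cos(5j)  | P4; PPI partner of g12 |
| g11 | 0.5·sin(12j) | not DE, shared P4∩P5 |
| g12 | 0.5·cos(5j) + 0.01·sin(7j) | P5; |r(g10, g12)| > 0.99 |
| g13 | 0.5·sin(8j)  | P5 |
| g14-g16 | 0.5·sin/cos(8j, 9j) | P6 |
| g17-g20 | 0.5·sin/cos(10j, 11j) | background, no pathway |

Pathways: P1 = {g01-g04}, P2 = {g03-g06}, P3 = {g06-g08},
P4 = {g09-g11}, P5 = {g11-g13}, P6 = {g14-g16}.

PPI edges (12): g01-g02, g03-g05, g07-g08, g09-g10, g12-g13, g15-g16
(within-pathway), g02-g07, g10-g12, g08-g14, g05-g09 (cross-pathway),
g01-g17, g18-g19 (involving background genes).

## Hand-derived expectations (alpha = 0.05, rho_min = 0.8)

Differentially expressed genes: exactly g01, g02, g03 (t ≈ 18, p < 1e-12);
every sinusoid-only gene has p ≥ 0.05.

Candidate pathway pairs and verdicts:

| pair | candidate via | verdict |
|------|---------------|---------|
| P1-P2 | shared {g03, g04}; PPI g03-g05 | **kept** — shared gene g03 is DE |
| P2-P3 | shared {g06} | removed — g06 not DE, no cross PPI |
| P4-P5 | shared {g11}; PPI g10-g12 | **kept** — |r(g10, g12)| ≈ 0.9998 > 0.8 |
| P1-P3 | PPI g02-g07 | removed — |r| ≈ 0.05 |
| P3-P6 | PPI g08-g14 | removed — |r| ≈ 0.12 |
| P2-P4 | PPI g05-g09 | removed — |r| ≈ 0.01 |

Final PIN: edges {P1-P2, P4-P5} over 6 nodes.

Greedy selection: P1's activity (PC1 dominated by the three shifted genes)
separates the classes perfectly, so step 1 selects P1 with CV-AUC 1.0; its
only neighbor P2 cannot improve on 1.0, so the search stops. Final marker
set: {P1}, final CV-AUC 1.0.
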