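# ACE2, author numbering of PDB entries 1R4L (closed) / 1R42 (open).
# Lips follow the published residue sets; the subdomain partition is a
# package-defined homology-based split (see region_preset documentation).
chain_id: A
lip1:
- [54, 81]
- [289, 296]
- [340, 346]
- [361, 370]
lip2:
- [109, 131]
- [143, 156]
- [267, 276]
subdomain1:
- [19, 108]
- [277, 425]
- [541, 571]
subdomain2:
- [109, 276]
- [426, 540]
- [572, 615]
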