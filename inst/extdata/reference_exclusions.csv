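"system","reason"
"BeSO4.4H2O","H...Be distance of 1.6 A; short-range cation electrostatics perturb the charge on H"
"ice II (three shorter bonds)","intra- and intermolecular coupling among three close bond lengths prevents unambiguous frequency assignment; only the longest bond is retained"
"ice IX (minor proton site)","low occupancy of the minor proton configuration"
"CuSO4.5H2O (coordinated water)","four of five waters coordinate to Cu2+; only the non-coordinated water is retained"
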