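>sp|P62258|1433E_HUMAN synthetic 255-residue stand-in sequence
RYSFVEYEHIFVVMFPLMIFCCEGPVIIDKMPFSEVEVPLAKAHVLWLDRDCDKVGAPAC
ESRAFEWWFGLPGMSQEHICMWWKIPDGDCSSVREHLVCRSEMSMLDVANMCHWLVGICF
VFHQCQNPAQNDTQIWDGKPRIQTRTYCNKKLMMEFFMMDTYTDGEFKQKEQNRTCRYWV
EKDTRERKWIGGFIRCQHIVMFMYVGWMHHHATSPCNPWWDCAKSQPQMIRPINFYIAYP
HPMFIWVPEFYGALF
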