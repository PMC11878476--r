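surface,canonical,category
donepezil,donepezil,medication
aricept,donepezil,medication
donepezil hcl,donepezil,medication
memantine,memantine,medication
namenda,memantine,medication
memantine hcl,memantine,medication
rivastigmine,rivastigmine,medication
exelon,rivastigmine,medication
rivastigmine patch,rivastigmine,medication
galantamine,galantamine,medication
razadyne,galantamine,medication
galantamine er,galantamine,medication
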