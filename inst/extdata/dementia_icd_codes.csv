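code,description
F00,Dementia in Alzheimer disease (ICD-10)
F01,Vascular dementia (ICD-10)
F02,Dementia in other diseases classified elsewhere (ICD-10)
F03,Unspecified dementia (ICD-10)
F05.1,Delirium superimposed on dementia (ICD-10)
G30,Alzheimer disease (ICD-10)
G31.0,Frontotemporal dementia (ICD-10)
G31.83,Dementia with Lewy bodies (ICD-10)
290,Dementias (ICD-9)
294.1,Dementia in conditions classified elsewhere (ICD-9)
331.0,Alzheimer disease (ICD-9)
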