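site,iso_ppm,group,doublet,iso_ppm_2
C21,211.5,nonprotonated,FALSE,
C3,187.8,nonprotonated,FALSE,
C5,171,nonprotonated,FALSE,
C1,155,methine,FALSE,
C2,132.4,methine,FALSE,
C4,126.2,methine,FALSE,
C9,103,nonprotonated,TRUE,101
C17,91.7,nonprotonated,FALSE,
C16,73.2,methine,FALSE,
C22,68.1,methylene,FALSE,
C13,50.7,nonprotonated,FALSE,
C10,48.2,nonprotonated,FALSE,
C14,44.8,methine,FALSE,
C12,41,methylene,FALSE,
C11,36.6,methine,FALSE,
C8,33.2,methine,FALSE,
C15,31.5,methylene,FALSE,
C7,30.8,methylene,FALSE,
C6,27.1,methylene,FALSE,
C19,26.4,methyl,FALSE,
C18,18.5,methyl,FALSE,
C20,16.1,methyl,FALSE,
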