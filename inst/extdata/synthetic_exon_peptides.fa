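>exon1
MAAAAAAAPSGGGGGGEEERL
>exon2
MVAGMLGLR
>exon3
EEKSEDQWQQSVCRLNKPWIQHDVWKFDCEYVRQDQELTVRSVIRWHQLPNRRNIFTRIW
AHPDNGICQSKCHENTLAEWMTSLIKPNKDERNRPSTLSSNWPGLK
>exon4
KRWALYRRLVWAGALRDSSNGTNRGSWHLQGHSILLRAVEWINIYWVICGHLYLVNPIAR
PAILTVIYPQNFTALWAGAAPEITVFYPTKCLWGMYQFYNSTTLWSFWEWIWAGCKPRWA
PHCRGNTLAQQHLPCYHSAWVIICGHLYPHFPWPPHHTRKQWFQHFHPYKISTQFQLKLN
PGKILPRAFATHGCPECYRPACQFFPHDRKLNIVYGSWSPRTQWAKINLFEGRTLAEHCF
GEHRAATTPLPFARWACVGRFEGNTNYGRHCKAESYRYPKTKGHVNQGQLVEITDTQVKT
KIGPPHGLRSGCARNPFWQEHCRPQDRGQENEYDHHYKRYCCSDWNTSPYRYIPTFNKAA
NGGPNFWFISR
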