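>isoform1
MVAGMLGLREEKSEDQWQQSVCRLNKPWIQHDVWKFDCEYVRQDQELTVRSVIRWHQLPN
RRNIFTRIWAHPDNGICQSKCHENTLAEWMTSLIKPNKDERNRPSTLSSNWPGLKKRWAL
YRRLVWAGALRDSSNGTNRGSWHLQGHSILLRAVEWINIYWVICGHLYLVNPIARPAILT
VIYPQNFTALWAGAAPEITVFYPTKCLWGMYQFYNSTTLWSFWEWIWAGCKPRWAPHCRG
NTLAQQHLPCYHSAWVIICGHLYPHFPWPPHHTRKQWFQHFHPYKISTQFQLKLNPGKIL
PRAFATHGCPECYRPACQFFPHDRKLNIVYGSWSPRTQWAKINLFEGRTLAEHCFGEHRA
ATTPLPFARWACVGRFEGNTNYGRHCKAESYRYPKTKGHVNQGQLVEITDTQVKTKIGPP
HGLRSGCARNPFWQEHCRPQDRGQENEYDHHYKRYCCSDWNTSPYRYIPTFNKAANGGPN
FWFISR
>isoform2
MAAAAAAAPSGGGGGGEEERLEEKSEDQWQQSVCRLNKPWIQHDVWKFDCEYVRQDQELT
VRSVIRWHQLPNRRNIFTRIWAHPDNGICQSKCHENTLAEWMTSLIKPNKDERNRPSTLS
SNWPGLKKRWALYRRLVWAGALRDSSNGTNRGSWHLQGHSILLRAVEWINIYWVICGHLY
LVNPIARPAILTVIYPQNFTALWAGAAPEITVFYPTKCLWGMYQFYNSTTLWSFWEWIWA
GCKPRWAPHCRGNTLAQQHLPCYHSAWVIICGHLYPHFPWPPHHTRKQWFQHFHPYKIST
QFQLKLNPGKILPRAFATHGCPECYRPACQFFPHDRKLNIVYGSWSPRTQWAKINLFEGR
TLAEHCFGEHRAATTPLPFARWACVGRFEGNTNYGRHCKAESYRYPKTKGHVNQGQLVEI
TDTQVKTKIGPPHGLRSGCARNPFWQEHCRPQDRGQENEYDHHYKRYCCSDWNTSPYRYI
PTFNKAANGGPNFWFISR
>isoform3
MTSLIKPNKDERNRPSTLSSNWPGLKKRWALYRRLVWAGALRDSSNGTNRGSWHLQGHSI
LLRAVEWINIYWVICGHLYLVNPIARPAILTVIYPQNFTALWAGAAPEITVFYPTKCLWG
MYQFYNSTTLWSFWEWIWAGCKPRWAPHCRGNTLAQQHLPCYHSAWVIICGHLYPHFPWP
PHHTRKQWFQHFHPYKISTQFQLKLNPGKILPRAFATHGCPECYRPACQFFPHDRKLNIV
YGSWSPRTQWAKINLFEGRTLAEHCFGEHRAATTPLPFARWACVGRFEGNTNYGRHCKAE
SYRYPKTKGHVNQGQLVEITDTQVKTKIGPPHGLRSGCARNPFWQEHCRPQDRGQENEYD
HHYKRYCCSDWNTSPYRYIPTFNKAANGGPNFWFISR
>isoform4
MYQFYNSTTLWSFWEWIWAGCKPRWAPHCRGNTLAQQHLPCYHSAWVIICGHLYPHFPWP
PHHTRKQWFQHFHPYKISTQFQLKLNPGKILPRAFATHGCPECYRPACQFFPHDRKLNIV
YGSWSPRTQWAKINLFEGRTLAEHCFGEHRAATTPLPFARWACVGRFEGNTNYGRHCKAE
SYRYPKTKGHVNQGQLVEITDTQVKTKIGPPHGLRSGCARNPFWQEHCRPQDRGQENEYD
HHYKRYCCSDWNTSPYRYIPTFNKAANGGPNFWFISR
>B5MCB4
MAAAAAAAPSGGGGGGEEERLEEKSEDQWQQSVCRLNKPWIQHDVWKFDCEYVRQDQELT
VRSVIRWHQLPNRRNIFTRIWAHPDNGICQSKCHENTLAEWMTSLIKPNKDERNRPSTLS
SNWPGLKKRWALYRRLVWAGALRDSSNGTNRGSWHLQGHSILLRAVEWINSAGLSIDVSF
GRARCVIHPMELIVGAGTCRVILSFCARSS
>A0A0D9SFX7
MVAGMLGLREEKSEDQWQQSVCRLNKPWIQHDVWKFDCEYVRQDQELTVRSVIRWHQLPN
RRNIFTRIWAHPDNGICQSKCHENTLAEWMTSLIKPNKDERNRPSTLSSNWPGLKKRWAL
YRRLVWAGALRDSSNGTNRGSWHLQGHSILLRAVEWINIYWSAGLSIDVSFGRARCVIHP
MELIVGAGTCRVILSFCARSS
>C9JH89
MVAGMLGLREEKSEDQWQQSVCRLNKPWIQHDVWKFDCEY
>A0A1B0GTV0
KRWALYRRLVWAGALGNTLAQQHLPCYHSAWVIICGHLYPHFPWPPHHTRKQWFQHFHPY
KISTQFQLKLNPGKILPRAFATHGCPECYRPACQFF
>A0A0D9SEX1
MVAGMLGLREEKSEDQWQQSVCRLNKPWIQHDVWKFDCEYVRQDQ
>H7BY72
MVAGMLGLNFAGAGVGQNSDAA
>A0A6Q8PHQ3
MVAGMLGLRFDTGPITAITHRRNYIMCVT
>A0A6Q8PF93
MVAGMLGLRSNNSLGNFAGAGVGQNSDAA
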