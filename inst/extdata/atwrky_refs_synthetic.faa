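>AtWRKY11
ELYLGFYEQGNRTLYLYEPAWRKYGQKMKEGLKVGLDPPIIPLRCVAVTNCPSPAYNDGSNMVTESAMSITIDVHTHTRN
DMDGIPPTKNFRTMRQLIGNDAQDDQAMGQEFAQVSRPNPSYFYSD
>AtWRKY14
IVRTLERYGWRKYGQKNDYPERCFTRSRCGMKNLLVVQDGKTIEMDKPMYKPHPHIYVNVDQRIQKSYSNVPFQGDYIPS
VYPPIGNGYIISSAESELPVPSVMLIATKKPPGFQRRSGDFTQMQNIVDEVNILQ
>AtWRKY18
GIMKIFNTAPEPPAYRDWRKYGQKYAFYPSQQRIIMCMDDPVCPNPPPYFKAILQIMAKSVYYEQNHAHLIEYPQSIYMA
FDFRVEPQTDLSPNEDIVQRGIRMGASQMQSFA
>AtWRKY20
KFQQLNVEDKGRFLDTMYSWRKYGQKYPEIDCLTRECQSEDMLIARGGNSMTDKADDAGFHKHDFAIERFGGPAYRFMER
KETWRKYGQKVRMQIDMESPVMYYRNQLEICGVLTCLFEELDKFEKAEILEPAYRFKSPHFH
>AtWRKY21
IPTTIPYRVWRKYGQKLGNQNTCGIMKNCGRSNGTFDLAMILTSMQPGYIFRHSHFMFAQPLSYFLFLNIGPDNLEIEKL
APDFMIYKDFRNLMASRPMNQQSIQASVMRYFPKEAGLYEG
>AtWRKY27
GSGGKRKMWRKYGQKFNDPKSQRRPPPTCPYGKRCNNIRRDNEQQQDQESKLEAMEITHSHGKVINEGLFQYRNDPYPIF
AVGGARYLYTEEALLRKFQGFSKIEDVVAPAKATMN
>AtWRKY28
VGFIYLDMARGTNFNSPPTSGYWRKYGQKSQVIPPLPMVPDRACADIICPKDVTSGITMQKEEDYSVLYTSAHMHPGANQ
FALYVAYLKATAKDTQQTSLNGYYMQYFYANLRVVR
>AtWRKY31
LKEEMSTRDDKNKFLYDYWRKYGQKEVGLIRDPQMPCKIEDRCNTVYPKQSVERMYNYVQKYSYDMHFHVMGFGAVEVSS
QFDIDSIAGAFKRGPTYARFFNLRVEIYSTSQ
>AtWRKY41
GPSTYAANQIDNNSKGVKLTWRKYGQKNGDQQMIDKTKPRAQMPNFCYFFDQMGCYRMTPAYQGVMMYIVTVAEPQNYHN
CIRRGGDERPLANRPSNMSPTISLESVMSVGGGYYDMTDRITSPAPYQMQLQFY
>AtWRKY43
DKLVGTSYFTGLPQPMAVTSFFMWRKYGQKSLRVPGICETGLCAAQRIYFMTQFIFKATFFFYDFSHTHGDPRPQTAMTG
FIRAEGKTTETDGRPEDVQRKTPLMYSEEVLNIE
>AtWRKY45
DQSVMLDIPYVGGVEIKYARRIMMNWRKYGQKYPVNCIEYVCQNTPMVLAKDYDTVQIMIMQYEKHKHMDEERQYLYMMN
VMKIEMSWRKYGQKMLTPVPQKAYENGEAISVCTLKFCEEFDPMNQANKKKFQLIYAYRVDHAH
>AtWRKY49
MMIELFQEFGGPFNSLWRKYGQKEYFAMLEITTVSRYDCIMYACASMQLKLSAVTQGKTAEDKPRFVHVHFFNVLTMGPY
GPTSNNRPTLFKVLTYVVADLLMILAPSTDSEPSMEEYANGVRGVRANTS
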