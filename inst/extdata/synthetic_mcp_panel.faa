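>Gokushovirinae_ref1
MQTDDKDDCYTQNAPGSLMYQIIYGHLLKFTNDKDLYCAPSQNVRVTNCKLFQCVRFDMKLHYTIYLEEW
KNPVHFIGWQSENDNNRFMRVYEKPMDHRWSVGAQMYWPITFFYKIPHQHAFMSMFNMYATFQFKWKLNF
YQEQWCLDGMAHWPSQCRYLNSAVGMRIPPANRFAAYLNGKCSTCINHGFKSGFQIINVQTAMEEHDMAR
RQKGLPQKMWQYIRPRIKHQEDKEDARWWNWEVHKYCIRQIIGSKLYKEKHAHSMRVGLLFPNLDNMRQS
PMLFVQWRNFTNGEYWCTFMKPIYKVRPQPPNVNRKQMHVCYMAPWFNVAFNVAVTLRNFNHNTPIRLKW
YVGINSPSAYASANTHDAMNNMRAYCMLIDWHTTFPWTPHGKNWWEGQGGYCMQWQHDAQWLRAWAVEES
KRHEDRMRCGSNSHPTDEPMKPEEKTEYLTVG
>Gokushovirinae_ref2
MQDTIKDDCCTQNAPGSLSYQIIYGHLLKFTNDKDLYCATCQNVRVTNCKLSQCVRFKMKLHYTIYLMEW
KNPTNFIGWQSENNNNPNMFVYEKPMDHVWSVCAQMYWPITKFYAIPGQHTFNSMFNMYAYFQCKWKLII
YREEWCLDIMAHWPSQCRYLNSAVGMRIPPAKIFAAYLNGKCSTCISHGFKIGKQYINVTAAMEEIDMAR
RRKVLPQKRIQYTRIRFKHQEDREDARWTNWENHKYCIRQIIGSKLYKEKARHSMRVGRLFPNTDTMRQS
PNLFVQWYNFTNGEYWCFLMKPIYKVRPQPPKVKRGQMYVPYMAPWTNVAFSDASTLRNFNHNTPIRLKW
YVGINSDSAAARANTYDAMNCMRVYDMLIDWHTTMPWTPHSSLWWEGQIGYCMQWQHDAQWLNAWAVEIS
KRHEDRDRCGANSEWPDLPYKPGEKTERLTVG
>Group_D_ref1
MKSFCCWAPGMVDMFTVYFTSYMGKVSEQPQDRVPQFTNKGRNPTCFMRRFNFGRYRAEGTHPHNRSHRK
YNMRKGYNRTVHDYGNGCNGLKMSWRNIHHGFSRYSQSNIVCGCWDSYMWGLKEKTQVCFNSKSIQFPEQ
DHCPMCIVAHCQMKWLLERFSVNLYKSMRGRCQNLKANSAVVYSEDTISFRKRHRFLDYEGYEIPANFHP
EFCYAVYGNRERVIVNDWVFIRKYLYWNFQPSSNSYMYLMGYMAWLPMSQLAFTRLPHCAYYMACKGAQR
LWYCLTFIWRKFVRTWKKMRWATNGCTQHLVTLAQEFVNPTVVRTGAKMKIECHDISDIHNLELLRMVVM
QMSVWTYFCDILNCDQHWDKFWLDFPFYEQHRNYCQMFWTISQMCNKCQREHYRLYQRCKCDQYEYQWHD
NWDLESHLCYHGEEPPIMHHEAQVWPFALIQNRDHCMQVKEFRWCYIYWGFLIQKK
>Group_D_ref2
MKSFCCVAPVHVDRFTVYRTSYWGKVSEQPQDRRRQFRNKIRNPTCAMRRFNGGRYPAEGTHAHRRFHEK
YNKRKYGNRIVSDYGNGCNGAKPSWRNPHHWFSRHSQKNQVCGCWDSYMWGLAEKTQVLFNSQSIQFPEQ
DHCPMYIVAHEQMKRLLERFSLNLYKSMVGRCQNDKAASAVVYSEDTISFRKTHLFLDYAGNEIPANFHP
ERCYAVYWNSERGIVNDWVFIRKRLYHAFQPSSNSLMYLMGYMTWVPMSQLAFDRLPHCIYYMACLGAQR
LWYCLTFCNWKKVRTWKCMRWAGCGCTQDCVILAQEFVNPTVVRLGAKMNIECHDISDIHNLEMLRMVVM
QMVVWTYFCDILNCDPMWDKDWLDFPFYWQHRYYCQMGWTISQMCWKTQREHYRIYQRCKCDQYEYQWHD
NQDLESHLCYHTNETPIMHHKNRFWPFALIQKEDHPMQTKAIRWCYIYDGFLIIKK
>Pichovirinae_ref1
MVHPKVDYMPVCWRRKHLNSWGCIVGKIYFDMYVMETHGHAMGCDCFVIGIQIIHEKINTAPCMIEQITQ
RAAWKFELDCIYNALVPPPGNKYYYAYCTPINVAGPQGAQRAEIQYAGHYQFEHIGQRIACTGTCHVEFM
LESYERRATWDVAPILYSMTMWVVDSKCCSPYCNITICMRNRRGCTVQHPSQDQLKIYKLASARDSPWLL
DKLCEQHPNPNCWKMQQMEYVVCISIVCFSYPAPEFSRKAYNYDRTLWLVDCMPMMCAKMWNKPPEAQYA
VPPAWAQDWCMSHVVPLVKNLIEGSLCIEWWDQLFYSMQHHETIYIQWVYAWHENEPQRNKELDSRVDDK
WDMHAMYQCKKKEWHAARDAWLRINTQEIVAFSYPICDGHTMIEMAIEHYKDMQVCDVLSECMIPFIETE
LNNCEDDVQDISFQCQSNNPQTSPESEYIEVTHWQCDEEPDNMELH
>Pichovirinae_ref2
MQDPKVDYMTVCWRRKPDNSWGCIYGRIYFDMYVMPTMGHALGCDCFVIGIQIIHEFINTAPCMIEQITQ
RAAWKFEPDCILNALLPPPGFKYEYAYCTPINVAGPQGAQRAEIQYAGFYQGEQIVQRIGKTGCTHVEFM
LESYERRARLKVAPILYSMTMWKVDGKCPSPYCNITICMWNYRGCTVAEPSQDQLKIYKLAVAGDYPCLL
DKVCEDHPNPNCWVMQQMRYVVCISIRCSAYPAPQFSRKAYNETRSLWLVDCMPMMCWQMWNKPPEAQYA
VPPAWAQDWCMSHKVPLVKNYIGQSLCITWQTQLFYSMQHVERIYRQWVYAWHGIEPQHNKALDFRVDDD
WDMVQMPCCKKKERMIARDAWVRINTQKIVAESYPICDGHTPIEMAIEHYCGMQVCDVLSECMIPFIETE
ENNCEPDGQFISFQCQSRNNQTSHESEYMEVTHQSNDEEPDRMTLH
>Alpavirinae_ref1
MCRTQYPARCGIQPILPKWLIFPAEKEWTDEKWFPNSFLAPFPMHYVKTPHAFIRERYMRKMPKPKIDTV
NHGNRHCWHFLFCAVKSQHDKYNTMNLATVRVIARRKVLYPSISEMQSTVWMVQDVYHGIKYVQARMIQI
HMAHADWWEYKGLVRAIMYLWHKYRLTRAPNFRNANIFSCHIQEHYFFRLVPCDEIIKFDKNACNCCWTE
QESYWQQHNVPEMRSKGRPTYQFMPGIARGPLPRRPLYPQWWSYHTVRSVAAINRGLQGPDSCKNTDAFW
YNNWHCDCKIDQCTCYNDGYQQWWWSQWAKLWDQPKKCRPRWDDILAFEIAPTEVVHGIMSLQHQADDLT
VFNLTDWVWHSGDTEVHIPIPFPRKAYVRTCKCGCRTSCPYQYDAYQI
>Alpavirinae_ref2
MCWTQYPARHHRDPILPKWLIFIAEKEWTDEYWFLKSFLRPFPMFYVKTPHDFTFCRYMRKMFRFTADTV
PHGNRWCWHFLFCWVASKHDSYNMMCLATVRVIARRKVLYPSESEMQLTVWMMQDEHHGIKPVQARMIQI
HMATAEWWEYKGLVRAIMWLWHKCRLTRAPNFRSAFIFVCHIQYHYFFRLVKTDYIIRFLKNACNPCWTE
QESYWQQHCSPEMRSKMRPTYQFMPGIARGPLFRRVQYPQWWSYHTVRSVAAINRGLQMGDSCKNADAHW
YNNWQCDAMINQCTCYNDGHQQWWWSQWAKLWDRPKFCRPRWDQILAFEWAPTEVGHGIISLQNQADDDT
VFNLTDWAYHSYKTEVHIPIGFPSSAYVRTCKCGCRFSFPYQYDAYQI
>Parabacteroides_prophage_ref1
MCWYNKEWGLDMIEELNEQHYILAIMWQINTSYRGKNAIYHVTNVWANWFHFVNAYNGEFRDMVMAMHNP
YKNKSRHGSCDRKFMMESQMDLHSKADSWKRWRIYVWKCHQDSQFYLIHYQTEYFYQSVSRKHASSCKDQ
YAFSRKKVFHLCEYINNRCWILFHPVKESAPIRYMVRICTSPKFTTHHSKEGADVFKGEHRPNDKWHNQQ
YKRIGLWYNVDGELQYVLKLRQGMWHDVQQCFDHHEHEFRCNHIQQQHNSWFASKHDYNFSVIIYSMELC
CPPPQFRDQIDCHSARCWDKMWQTIGWGPLYMGFDYKENAIQEKQEWQYLRDPCLGSYMQVEQFDYRKQY
VHNYTLKTCQWMWDTCCWDYNWREYHPEEQTASLENMCLREFQGKVTQFATNDKQNTVHLVCKGSQHAWY
GWGVKCFDPEERKPCPSVFLHFVHCSQRYRPYQQHTKWKRCS
>Parabacteroides_prophage_ref2
MCWYNKEWGRDMIEELNEQHYCLAIMPQINMSYRGKHARQHVTGVWANWWHFVNAYNPEFGHMVMAMHPP
YLNMSRHGSCDRKFLMESRMDSHSKVNSWKRWRMYVWKCHQDSQFYLIRGHTEYMMQSVSRKHQSSCKDQ
YAFSRKKVFHLCVYINEYCWILFGPVKWLAPIRVNVRLKDSRKRTVHHKKEGADVFKGEMRPRDWWHNQQ
YKRIDLWYNVEIELQHVLKLRQGMWHGVQCCFDHHEHEFRCVHIQQQHNSWFADKHFYWFSVIIYSMERC
CPEAQFRDQIDMHSANCWTKMWQTIPWGPLIMGFQYKENAPQEKQEWQYLRDPHLGRCMQVEQFDYRKQA
VHSLTLKTCQWMWDTCCWDYNWHEYCPEEQTASLSNCCLREFTSQVTQFATIKKQWTVHLMCKGSQRPWK
GFGVKCFDPENRKPCPDVFLHFVHCSQRYRPYNQHTIAKRCY
>Pequenovirus_ref1
MKANCTWQTQWTAIALSQDEIDHKLGHIPHYKFKTDMPNCKTTWAQTPRGLAYLLWSPYGVVLYIDNLWD
AQENGEQTWINCHISVFILMAGPAIYRRMGYPIHICQTNHPCLLGECCTRRMCDVMNRNNHARRKNCQFW
NYDFHLLMWSKTQSHFPYNFPMFELTCLLAKSLMIYGALFIGVTPRIGDTTVTVRPKRAGKRYDIPVNAC
MAGCPDISGWMGDGSAGARNIGRDCHLKFFPQSIFNHINTSWCLVNCWVGCEFFIQTDFKFTRWKIFVAD
AWNGPDWPQKDLWQQDSMHRYKKCYSCDPNCCGTCTHWGGREPKLIVLLWWCHTDNMKCLLGVVMQCPFD
CIRLQPCRSTQIASTVCKWIRTLTAQLDLDYLIVFPGKRGKSMQFTWKQGYTHK
>Pequenovirus_ref2
MKANCTWQTQETAIALSQDEIDHKLGHIPHIMFKTDMPNCKTTWAQERIHLAYLLWTPIGVVLQIDNHWD
AQENGEQTWIPCHISVCIMMQQPLIYRRMGCPIHICQTQHPCVLGECCTRRACEVMNRNNHARRKNCQFN
NYDSHLLMWSKTQIHIPYNFWMFELTCLLAASLMEYGALFIGVTPRIGFYTVTVRPNRAGKRYDIPVNMV
MAGCPSISGWMGDGSAEQRDFGRDCHLKFFTQSIFNINYTSWCLVNCWVGCEFLIQTDIKVTRHKIFVDD
SLNGPDWPQKDLQQQSSMHRMPKKYSCDPMCCKTCTHRGGREPKLIVLWMWCHTWNMKCLWNVVEQNSFD
LIRSQDQRSTQIAATVQKWIRTLTAQLDMNALIVFPGKRGKYMQFAWRQGKCQK
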