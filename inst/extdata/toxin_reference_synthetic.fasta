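>3FTx_ref synthetic three-finger toxin reference
MFLFAWCVMCWWAWIWCVACLNHRGWHKIGLSNSYMNACNFEVHWTARCDAGPKPRNGKSEINRYKICAHSSNWRINWSM
SCWTLTIFDQSP
>SVMPIII_ref synthetic snake venom metalloproteinase P-III reference
MFMMACCCWCLIWCIFAIAVCFIYQFEHIMTTSFNPELFLGETPGQSDSDLFRIAIQDFYHNTDNGTKTSAIHPEMECGA
FCPRDVAQFYRIMNFDEPNFNSMNPKADGEQARVCCGTRLKEHIIPLYQDFKVFDWKDTNHAIDKQKDMCHACENRENFC
PDNLNQKCNYIECPKATHWYDTIGFKHRLCWWIQVHKVHSFNSQQGMQVISFYMYEPCGWEPAFCYNQSGCNKYWQPTGQ
SYVHGAPQCCNYFCCNTCQPHGEQNCPVLLAQRVHWYRYPAENVEKMQLEINLRAHKMCCRQKKCLHQNMMCEAQWNPQF
MWACIWAGEPKDCIWHCIYQRGTEVLTTGAEGSPAWCRVKPWMLWTHPEYIFHSYAMWHDDQFLMFYMIMGRAQPVAKPP
MRRKEAWAFCDNSHCTSHWMPIGMRAAHDQFCSLPYLETHGLRGYMFRHIHGFLLIEFYGNCLWPSPTQYPMRAESNFWT
QKMICFGMETWHAHMWAMMNFVFRLLNNMPKDDFDIRNNQMHTDPPICMTFNSEAMFEWTLQWQGYMTANRRPKVMGRKY
MRQEVNEFTIIYSWMGVKKHNMGMLDLFGVHATGDWNDLSQYIKNQKAET
>CRISP_ref synthetic cysteine-rich secretory protein reference
MMMVCFFIAIWLVWVLLMLCFKHAVMCCCAPMPDCQYVCADCFLGHKDIMAPQFKIRHPQVYAQPHNIMLMMLTVLFAWE
QTGRHNPIYPGNHDVDTIQGCWGKDVCGLGCQHEYNFQSVICHHLHHLDVPRFADQIQAPMIVWPAMYYPQVMDWAMMDY
GTMWLFVSNCKMMCDIPAQRDQMVNMHYELLRQENCLLFDRHFFLLGLRFHELCSELIQPYTIMWLWWTACCPFYKGLQ
>CTL_ref synthetic C-type lectin toxin reference
MFCAWIVIFAMLWAAMFCCCETMNWQADMPGPEPLGYGGATSAMNILQYEVTTKIMTCQLLKNTPCYVSPFNWNSVSSEL
VDHKSNMLGQDQLKFVDWSHHNLLSTDALTGVNQSRVKRSRNQNDYILFRRSMTIDYPNMKWDTIQEQCGHYGRKLEM
>Ficolin_ref synthetic ficolin toxin reference
MMIWCVFLWVMVAIAIWWFFKKAHKKTCTMSDKMGGNNVSHMIPCDDVQEWVATVFIFYWTDWSTRDVLDMCMVCTAWRH
QLDIIQLRTMQYRAMNSWYNLHAHGTINPNENIQTTNQTIHLWNTWWGYWMKANQWGQRLDWLQKPRLQIHYEKVDQCGR
NWVQALTDHWEDKENFPFSYAWVVDHQHIEPDWTIKYYVGDTHDLDMHQRPPNKGALHLDFDFMDISEFDWDDAGEDGNC
TTEYNGYIQIMYSGKMLMMLKMIFLNDSCVQFKIIQMKEQWSCNWIYCKHMTEGLDYLHWETNPTEAWIPHKLWSHTIFY
AKARFMQIFVPT
>AChE_ref synthetic acetylcholinesterase toxin reference
MIAWWICAWCCICIFLLFVAPVNMRLSWIRKHLGIRPQIRNVGCTRWREHTPMQGFRSDYFCTCRSLTAQYYNVMRYHQK
PNYNFPHLDFKQFQICCEYEIMIGWQMLMGKAYVSQNDWIDESDDARTYEEMWFVVAQDDDEAKWKKIEWKFYLELKADV
HVKKESKHGFKDIDHFEFALTTEGIGMSREWCKRKVLAIVENNYYICNTSMWGYNSYSFMKSHTIKRTCVHKCRPPCIDD
QQRVIFDSFCGKDTWQAKNVANHCKFMVTEAKVDDTEAYVYFNHSKMWAAWSHAHVWNVPKQVFPICASPDMQHQPITFV
CKESEYVYCNQMPIFKTCQWLLVCYTFWYDQYKDVAMMDNWGLTSGDIHDCFFHLSYTNRQIESMYCTKFICAINQAPMV
FAFMQASSYCECFATHWQNAVIPINQEEYKQIEGKICKPNLYLWRVVKDRKVQIVSSERHVLAWYQRAMDLHITFDIGPT
TGTSTMDSQWKCGANFKYGGGRKICLAWGRWHDNVCSKMSITHPRARQAKAFNKNVEPCIYCWFWNKRHWWLLLSSFRNE
YVVANSLHYFQEGAYIAISSRED
>NP_ref synthetic natriuretic peptide toxin reference
MWFVVCIVMFFIVVLIMILAPRVAGHVAAFQKYDHRWRYNICVVKAWLMINVLKCWIKWIQSKTFYKPWVRHKSHIWCVA
DCCGWRMMNQKPVVWLKNPFYACCCMDLNGVNLTQVTVKKQWCPQVVWDFSYATLVDTEFQFDRKDTWKNWEYAQPFEFH
YRCQCSFSCYNASHYGK
>KUN_ref synthetic Kunitz-type protease inhibitor toxin reference
MCCAVMAWCMILCCMFLWAIITWWWMNHFFYKMNYKCRHCIHSENTNQHSNMHPAYPGPTGHLYWTQIGWYTERQMRLLS
SLRHIQEVTVRALIERRPFTIDFFWYGIWKHYTLFPIKCIIWNWTHEPYVRKSSTHTITKPYSNRAPFTVKCICMPWAHT
MLSMRYACMLPGCDNHWEDV
>VEGF_ref synthetic vascular endothelial growth factor toxin reference
MIAMFAFCILVFWLVFFAWMMDARVEPKLWKTWAPSEVQLFCCMPIKMTFHLAWAHPLYKKQFIIVGIIACYCVVWIPKL
RAILEMKCLYHLNMHEISNGPWCRMIPIDNKQATHNKELHFLHETGRKIKLNKSLKFFLQPDLPAIWPRMLFVMIFKWAA
EAWQNHVRIWIPGFENMNNNYYADCINHQYTC
>Waprin_ref synthetic waprin toxin reference
MWFLVCAMWVIICICICMLCQHGQPTHIECWKESQEFCYFAIHLEREDSCFGTRMQKWGAVHTGAHCKHANPTQICELAN
FCWDFNGMQCMTQNNAMNKDIAKVICWNEAKVLYLDDWADWTWRDSMIGNAGYET
>PLA2_ref synthetic phospholipase A2 toxin reference
MMCWAWAVVLAIFFIFWWACIVEDISVVLCFRDQFYGTCCRPNWRMWIGPISAHRFWKMDPCKMVNQWISCKVGGNDTHW
YEQDKQNTCWVCPLSVQLACPCLIEMCHKYKLGIGMQHHWYCLRVMHRPRFIRLHNRWSNWHYQMDIWFYH
>CF_ref synthetic venom coagulation factor reference
MCFWAFLLCFVLILICCWVCTDRLGRATVRVFDECCNCWTASQVGNFVCNPIGFNKHVFLYGTRRLEIAMAYMTANSDDV
HWMAKHNARGYSMYEEATDGDPRFSTSPVVGCGCPTCLKAATQHDMSDQQYCNTSWEGRAENPGMPQIANVSLVSVFLES
QHLTVTHHALHGKMYQKCWKYNWVATVSKAFFDFKVMYPNTIMEMNFDYPYFQICWKWLEFTDDYSAWFHRNACIETEAD
APHYMIIHWNIFFVNYLFHHLRIFHMWCHYMKGKFVYFQENHASCCFKWFQDHMCMFYTWIYIWTCRYQMNKQEVFMRFM
LHCTAWSKFAGDMICYAWDLQHGENMVSVYPYNLSEIYKIASWTRSNNGSVQYEFHTQCWFTWKQISYNLEMMNEPNLSF
KNAKTDTKPSYARDMRTIFQMYEDFLHNEF
>VF_ref synthetic venom factor reference
MVMILIACWVWVIFCCMVLVPHECVYNVYRYHRWINSTDTDCQLSSWDNTDFMEERCENNDPESPYTDVTVCMMYWKHRN
WVHHPMYANCVTGIGFACCYYQEKRWFLRFYVATVPGFNNRHMDTKPFVAACDKVCQRAQQDIAYATCVCKTRRWPVYWK
WTVFAVGGMDRAENWKQEGTHRISWENSCHMHRITKKAEASHDWPYYTFLRADMDWEDIQSMVNREGCNRKEAYMIKEVQ
LKETRYKTLWEQYMFITGGAPGEIGDKNNHCGVMQNVQTDVEPKQTPLYCRPGCEHMGDHWFVFVNRRFNVHLWEGIYKN
ELIDSGYHQQHMWYDHWGRCHNTWPICHHILSKGDSPMMKWPMPPWKWGPYATYPLMDFTLGMQWQSPFLWNKVARNSMH
PTNIDTRSFAFLRRYSHWMPVWEVLFLIPNRSAKHEWKAFYCYECTYKAIKCVACDQITYIEACHEFNIPSWASQMEEFC
IIISYCSINFMYMGATWFDGWDKWIVSPMMFVWAFWVVHDAGKHCVASMKDACDDPEINQMIHNNIVHGCHAGARGWQQR
YDDLGIYIHKIKYWKIQVQMIKGNWAADHRTLYRISYIPP
>HYAL_ref synthetic hyaluronidase toxin reference
MWVFVMVLFFIAFCFWAFALKHQHWWMLERMNCWHSIHTQAHGSYRKASWIGHEDPYTREVPAEWPCRWENDNWVCFARF
FVQSMKIAMTHQMWMHKQRCMEGNRYLHFEYEHRPPPIMVHHILKLEHIVAFTMWELIVQRFHQHQAGHMALVYHSVTNS
MAFPGDLLLEYIVPISYEITVVCSKARKNFGAHSNRPHQKGWRINFRNKVGVNMDDDKCLLCPLMVYPLQHEKETGSNVS
PPDGMVQNWVNKEHGMAYNINDTYNYWRLAAHGVVQGEVPTFCWGLGGHNVMIQALVDNFHYSFPPIKTFMWMIAVRCEH
QLGIMWKAQNFTMWAIDIWCNNQHKSDGTGMLGIDLVCEEWLQGYRCLAEAHTQECAEKMYPMKLAENSNVSLCFNTTEY
VRLYARHIYGGPAVYYFQHLRMNITPDHKARHTAQMNMTHHMVYNRM
>PDE_ref synthetic phosphodiesterase toxin reference
MLCCMCVILIAVVCICFWFVWNDIGKAEAQAESNYVQTLWIGLAMYRDYPSNTLQCLMWTIMRKMHGLHLIEDIGDAVWQ
QMCPSVDSQDVCDDIPYVETFDLFVCDKHERMPQRAGPSWGKDKMRYWMRPADAMQANYKHKWCGLQNLLEATPSTERWY
KNKYHFPTSRYATTFVGCTMQFHIVKNGHTFARCAQDDQISIRNSWKKDEPQLRETISTFDTSCDKFPNNKWQCSRQDTY
KSAEGDWEQWAFKRLLKAVGLCKHTDRFYNNMGRCFFFTYTFLPGTRFMNHIKEVSYQVGLCRFNQFVPVTPLKVWKPIK
RMWNMVDHSGGQQASLIYAGQFFAHTPYIIVPLVHRVMTWRAVFWMHACPMTRPTAAPNPVKSSMGRTQCGRPQAAAHHM
CYGVLYKVVGMEPHAHGRLIVRTKGATELVLMTARYYPFIRMEANTTVWLNCY
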